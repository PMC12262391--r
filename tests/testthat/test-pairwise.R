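test_that("group pairs validate disjointness and resolve ids", {
  x <- random_matrix(4, 6, 2, seed = 1)
  gp <- group_pair(c("bs1", "bs3"), c("bs2", "bs4"), x)
  expect_equal(gp$group_a, c(1L, 3L))
  expect_equal(gp$group_b, c(2L, 4L))
  expect_error(group_pair(1:2, 2:3), "disjoint")
  expect_error(group_pair(integer(), 1L), "non-empty")
  expect_error(group_pair(c("zz"), c("bs1"), x), "unknown biosample")
})

test_that("joint background pools both groups", {
  # one row all state 1, one row all state 2 -> pooled q = (1/2, 1/2)
  x <- make_matrix(rbind(rep(1L, 5), rep(2L, 5)), n_states = 2)
  gp <- group_pair(1L, 2L)
  expect_equal(joint_background(x, gp)$q, c(0.5, 0.5))

  # identical group composition: joint equals each group's own background
  y <- make_matrix(rbind(c(1, 2, 2), c(1, 2, 2)), n_states = 2)
  expect_equal(joint_background(y, group_pair(1L, 2L))$q, c(1, 2) / 3)

  # convex combination of group-wise backgrounds, weighted by group size
  z <- random_matrix(5, 10, 3, seed = 3)
  gp2 <- group_pair(1:2, 3:5)
  qa <- tabulate(z$states[1:2, ], 3) / 20
  qb <- tabulate(z$states[3:5, ], 3) / 30
  expect_equal(joint_background(z, gp2)$q, (2 * qa + 3 * qb) / 5,
               tolerance = 1e-12)
})

test_that("signed squared distance evaluates the printed formula", {
  # identical columns in both groups -> zero everywhere
  x <- make_matrix(rbind(c(1, 2), c(1, 2), c(1, 2), c(1, 2)), n_states = 2)
  tr <- ssed_scores(x, group_pair(1:2, 3:4))
  expect_equal(tr$ssed, c(0, 0))

  # hand-built saliency vectors via a designed background:
  # group A all state 1, group B split -> sA = (1*log2(1/q1), 0)
  q <- chromsaliency:::.state_background(q = c(0.5, 0.5))
  y <- make_matrix(rbind(c(1L), c(1L), c(1L), c(2L)), n_states = 2)
  gp <- group_pair(1:2, 3:4)
  tr2 <- ssed_scores(y, gp, background = q)
  # sA = (1, 0); sB = (0.5*log2(1), 0.5*log2(1)) = (-0.5, -0.5) is wrong:
  # p = (1/2, 1/2) = q so sB = (0, 0); distance (1-0)^2 = 1, A higher
  expect_equal(tr2$ssed, 1)

  # B more salient flips the sign
  tr3 <- ssed_scores(y, group_pair(3:4, 1:2), background = q)
  expect_equal(tr3$ssed, -1)
})

test_that("swapping the groups negates the statistic at every bin", {
  x <- random_matrix(6, 40, 3, seed = 5)
  a <- ssed_scores(x, group_pair(1:3, 4:6))
  b <- ssed_scores(x, group_pair(4:6, 1:3))
  nonzero <- a$ssed != 0
  expect_equal(b$ssed[nonzero], -a$ssed[nonzero])
  expect_equal(abs(b$ssed), abs(a$ssed))
})

test_that("all-quiescent bins are flagged for exclusion", {
  states <- rbind(c(2, 1, 2), c(2, 1, 2), c(2, 2, 2), c(2, 1, 2))
  x <- make_matrix(states, n_states = 2, quiescent = 2L)
  tr <- ssed_scores(x, group_pair(1:2, 3:4))
  expect_equal(tr$excluded, c(TRUE, FALSE, TRUE))
})

test_that("permutation null recovers known sampling distributions", {
  # pipeline sanity: exchangeable groups give a null location near zero
  spec <- simulation_spec(4, 10, 3000, state_freqs = c(0.2, 0.15, 0.15, 0.5),
                          seed = 21)
  x <- simulate_matrix(spec)
  gp <- group_pair(1:5, 6:10)
  fit <- permutation_null(x, gp, n_perms = 20, sample_size = 20000,
                          n_fits = 3, seed = 7)
  expect_lt(abs(fit$loc), 3 * fit$scale / sqrt(20000))

  # the same seed reproduces the same fit
  fit2 <- permutation_null(x, gp, n_perms = 20, sample_size = 20000,
                           n_fits = 3, seed = 7)
  expect_equal(fit, fit2)

})

test_that("p-values follow the fitted two-sided tail", {
  fit <- structure(list(loc = 0.5, scale = 2, shape = 2, nll = 0, n = 100),
                   class = "gnorm_fit")
  bins <- genome_bins(c(chr1 = 4))
  tr <- structure(list(ssed = c(0.5, 1.5, 3, 10),
                       excluded = c(FALSE, FALSE, FALSE, TRUE),
                       state_contrib = matrix(0, 4, 2), bins = bins,
                       model = state_model(c("A", "B")), pvalue = NULL),
                  class = "differential_track")
  out <- empirical_pvalues(tr, fit)
  expect_equal(out$pvalue[1], 1)                       # at the center
  sigma <- 2 / sqrt(2)
  expect_equal(out$pvalue[2],
               2 * pnorm(1, sd = sigma, lower.tail = FALSE))
  expect_equal(out$pvalue[4], 1)                       # excluded bin
  expect_true(all(diff(out$pvalue[1:3]) <= 0))
  # normal-tail closed form: |x - loc|/sigma = 1.959964 -> p = 0.05
  p05 <- empirical_pvalues(
    within_tr <- { tr$ssed <- 0.5 + 1.959964 * sigma; tr }, fit)$pvalue[1]
  expect_equal(p05, 0.05, tolerance = 1e-6)
})

test_that("BH adjustment steps up over non-excluded bins only", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  adj <- bh_fdr(c(0.01, 0.5, 0.02), exclude_mask = c(FALSE, TRUE, FALSE))
  expect_equal(adj[2], 1)
  expect_equal(adj[c(1, 3)], p.adjust(c(0.01, 0.02), "BH"))
  # adjusted values never fall below the raw p-values
  set.seed(31)
  p <- runif(50)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("a planted differential region is recovered as the top hit", {
  freqs <- realistic_freqs(6)
  spec <- simulation_spec(6, 10, 4000, state_freqs = freqs, seed = 41)
  # group A gets an enhancer-like rare state, group B stays quiescent
  spec <- plant_group_differential(spec, 1:5, 6:10, start_bin = 1500,
                                   n_region_bins = 25, state_a = 5L,
                                   state_b = 6L)
  x <- simulate_matrix(spec)
  gp <- group_pair(1:5, 6:10)
  track <- pairwise_analysis(x, gp, n_perms = 50, sample_size = 20000,
                             n_fits = 5, seed = 17)
  regions <- top_differential_regions(track, region_size = 5000, k = 10)
  tab <- regions$regions
  expect_gt(nrow(tab), 0)
  planted_start <- (1500 - 1) * 200
  planted_end <- planted_start + 25 * 200
  expect_lt(tab$start[tab$rank == 1], planted_end)
  expect_gt(tab$end[tab$rank == 1], planted_start)
  expect_equal(tab$direction[tab$rank == 1], "A")  # A's rare state is salient
  # regions are mutually non-overlapping
  if (nrow(tab) > 1) {
    tab <- tab[order(tab$chrom, tab$start), ]
    same <- tab$chrom[-1] == tab$chrom[-nrow(tab)]
    expect_true(all(!same | tab$start[-1] >= tab$end[-nrow(tab)]))
  }
  # the planted bins survive FDR control
  idx <- 1500:1524
  expect_true(all(track$qvalue[idx] < 0.05))
  # the sign in the region is positive: A's state is globally rarer
  expect_true(all(track$ssed[idx] > 0))
})

test_that("zero-score tracks yield no differential regions", {
  x <- make_matrix(matrix(1L, 4, 60), n_states = 2)
  tr <- ssed_scores(x, group_pair(1:2, 3:4))
  rs <- top_differential_regions(tr, region_size = 2000, k = 5)
  expect_equal(nrow(rs$regions), 0L)
})
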