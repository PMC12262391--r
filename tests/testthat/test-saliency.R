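test_that("expected frequencies count all (biosample, bin) entries", {
  m <- make_matrix(rbind(c(1, 1, 2, 2), c(1, 2, 2, 2)), n_states = 2)
  expect_equal(expected_frequencies(m)$q, c(3, 5) / 8)
  # constant matrix puts all mass on one state
  expect_equal(expected_frequencies(make_matrix(matrix(1L, 1, 4),
                                                n_states = 2))$q, c(1, 0))
  # invariant to bin order
  perm <- make_matrix(m$states[, c(3, 1, 4, 2)], n_states = 2)
  expect_equal(expected_frequencies(perm)$q, expected_frequencies(m)$q)
  # pseudocount regularizes zero-frequency states
  expect_true(all(expected_frequencies(make_matrix(matrix(1L, 1, 4),
                                                   n_states = 2),
                                       pseudocount = 1)$q > 0))
})

test_that("observed frequencies are per-bin biosample fractions", {
  m <- make_matrix(cbind(c(1, 1, 2)), n_states = 2)
  expect_equal(observed_frequencies(m, 1), c(2 / 3, 1 / 3))
  single <- make_matrix(cbind(2L), n_states = 2)
  expect_equal(observed_frequencies(single, 1), c(0, 1))
  expect_error(observed_frequencies(m, 9), "out of range")
})

test_that("basic saliency evaluates p*log2(p/q) with the 0 log 0 convention", {
  # p = q at every bin -> all scores zero
  m <- make_matrix(rbind(c(1, 2), c(2, 1)), n_states = 2)
  expect_equal(s1_scores(m)$per_state, matrix(0, 2, 2))

  # p = (1, 0) against q = (1/2, 1/2): 1 * log2(2) = 1 bit
  q <- chromsaliency:::.state_background(q = c(0.5, 0.5))
  one <- make_matrix(matrix(1L, 2, 1), n_states = 2)
  s <- s1_scores(one, q)
  expect_equal(s$per_state[1, ], c(1, 0))
  expect_equal(s$total, 1)

  # p = (0.25, 0.75) against uniform q: (-0.25, 0.43872), total 0.18872
  mx <- make_matrix(cbind(c(1L, 2L, 2L, 2L)), n_states = 2)
  s2 <- s1_scores(mx, q)
  expect_equal(s2$per_state[1, ], c(0.25 * log2(0.5), 0.75 * log2(1.5)))
  expect_equal(s2$total[1], 0.25 * log2(0.5) + 0.75 * log2(1.5))

  # observed state with zero background and no pseudocount is an error
  qz <- chromsaliency:::.state_background(q = c(1, 0))
  expect_error(s1_scores(make_matrix(matrix(2L, 1, 1), n_states = 2), qz),
               "zero background")
})

test_that("pair background enumerates ordered distinct biosample pairs", {
  # all entries a single state
  const <- make_matrix(matrix(1L, 3, 4), n_states = 2)
  pq <- expected_pair_frequencies(const)$pair_q
  expect_equal(pq, rbind(c(1, 0), c(0, 0)))

  # single bin, column (A, A, B): 6 ordered pairs, 2 each of AA/AB/BA
  col <- make_matrix(cbind(c(1, 1, 2)), n_states = 2)
  expect_equal(expected_pair_frequencies(col)$pair_q,
               rbind(c(2, 2), c(2, 0)) / 6)

  expect_error(expected_pair_frequencies(make_matrix(matrix(1L, 1, 3),
                                                     n_states = 2)),
               "at least 2")

  # normalization and symmetry on random matrices
  for (seed in 1:5) {
    x <- random_matrix(4, 7, 3, seed)
    pq <- expected_pair_frequencies(x)$pair_q
    expect_equal(sum(pq), 1)
    expect_equal(pq, t(pq))
  }
})

test_that("per-biosample pair background is consistent with the pair background", {
  # identical rows put mass only on diagonal state pairs
  same <- make_matrix(rbind(c(1, 2, 1), c(1, 2, 1)), n_states = 2)
  q4 <- expected_pair_sample_frequencies(same)$pair_sample_q
  off <- q4[1, 2, , ] + q4[2, 1, , ]
  expect_equal(sum(off), 0)

  # hand enumeration: rows (A,B),(B,B) -> 4 events of weight 1/4
  x <- make_matrix(rbind(c(1, 2), c(2, 2)), n_states = 2)
  q4 <- expected_pair_sample_frequencies(x)$pair_sample_q
  expect_equal(q4[1, 2, 1, 2], 0.25)
  expect_equal(q4[2, 2, 1, 2], 0.25)
  expect_equal(q4[2, 1, 2, 1], 0.25)
  expect_equal(q4[2, 2, 2, 1], 0.25)
  expect_equal(sum(q4), 1)

  # marginalizing over biosample pairs recovers the pair background
  for (seed in 1:5) {
    y <- random_matrix(3, 6, 3, seed + 10)
    bg <- expected_pair_sample_frequencies(y)
    expect_equal(apply(bg$pair_sample_q, c(1, 2), sum), bg$pair_q,
                 tolerance = 1e-12)
  }
})

test_that("pair saliency matches brute-force enumeration", {
  # a bin whose pair distribution equals the background scores zero
  swap <- make_matrix(rbind(c(1, 2), c(2, 1)), n_states = 2)
  expect_equal(s2_scores(swap)$total, c(0, 0))

  for (seed in 1:8) {
    x <- random_matrix(3, 5, 3, seed + 20)
    expect_equal(s2_scores(x)$per_state, oracle_s2(x$states, 3),
                 tolerance = 1e-9)
  }
})

test_that("biosample-pair saliency matches brute-force enumeration", {
  # columns all identical -> per-bin joint equals background -> zero
  const_cols <- make_matrix(matrix(c(1L, 2L, 1L), 3, 5), n_states = 2)
  expect_equal(s3_scores(const_cols)$total, rep(0, 5), tolerance = 1e-12)

  # hand-enumerable 2x2 case
  x <- make_matrix(rbind(c(1, 2), c(2, 2)), n_states = 2)
  expect_equal(s3_scores(x)$per_state, oracle_s3(x$states, 2),
               tolerance = 1e-12)

  for (seed in 1:8) {
    y <- random_matrix(3, 6, 3, seed + 30)
    expect_equal(s3_scores(y)$per_state, oracle_s3(y$states, 3),
                 tolerance = 1e-9)
  }
})

test_that("KL totals are nonnegative under same-matrix backgrounds", {
  for (seed in 1:5) {
    x <- random_matrix(4, 8, 4, seed + 40)
    expect_true(all(s1_scores(x)$total >= -1e-12))
    expect_true(all(s2_scores(x)$total >= -1e-12))
    expect_true(all(s3_scores(x)$total >= -1e-12))
  }
})

test_that("scores are invariant to biosample row order", {
  x <- random_matrix(4, 8, 3, seed = 77)
  perm <- make_matrix(x$states[c(3, 1, 4, 2), ], n_states = 3)
  expect_equal(s1_scores(perm)$per_state, s1_scores(x)$per_state)
  expect_equal(s2_scores(perm)$per_state, s2_scores(x)$per_state)
  # S3 backgrounds are per biosample pair, so the total is preserved under
  # a simultaneous row relabeling even though per-pair terms move
  expect_equal(s3_scores(perm)$total, s3_scores(x)$total, tolerance = 1e-12)
})

test_that("for fixed p the per-state score decreases in q (rare states weigh more)", {
  p <- 0.4
  qs <- seq(0.05, 0.95, by = 0.05)
  vals <- p * log2(p / qs)
  expect_true(all(diff(vals) < 0))
})

test_that("consensus picks the most salient state, dominant the most frequent", {
  expect_equal(consensus_states(score_track(rbind(c(1, 0), c(0.2, 0.2)),
                                            genome_bins(c(chr1 = 2)),
                                            state_model(c("A", "B")))),
               c(1L, 1L))  # second bin ties, lowest index wins

  m <- make_matrix(cbind(c(1, 1, 2)), n_states = 2)
  expect_equal(dominant_states(m), 1L)
  tie <- make_matrix(cbind(c(1, 2)), n_states = 2)
  expect_equal(dominant_states(tie), 1L)

  # dominant agrees with consensus under a uniform background only when
  # argmax p also maximizes p * log2(p / q); check by brute force
  for (seed in 1:5) {
    x <- random_matrix(4, 8, 3, seed + 50)
    qu <- chromsaliency:::.state_background(q = rep(1 / 3, 3))
    s <- s1_scores(x, qu)
    for (b in 1:8) {
      p <- observed_frequencies(x, b)
      expect_equal(which.max(replace(p * log2(p / (1 / 3)), p == 0, 0)),
                   consensus_states(s)[b])
    }
  }
})

test_that("a rare shared state out-scores the common dominant state", {
  # 2 of 20 biosamples share a state that is rare genome-wide; its
  # saliency level beats the common state's despite lower frequency
  set.seed(9)
  m <- 20L; B <- 500L
  states <- matrix(sample.int(2, m * B, TRUE, prob = c(0.985, 0.015)), m)
  states[, 10] <- 1L
  states[1:2, 10] <- 2L
  x <- make_matrix(states, n_states = 2)
  s <- s1_scores(x)
  q <- expected_frequencies(x)$q
  expect_lt(q[2], 0.05)
  expect_equal(consensus_states(s)[10], 2L)
  expect_equal(dominant_states(x)[10], 1L)
})
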