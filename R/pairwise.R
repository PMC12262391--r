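#' Define a pair of biosample groups
#'
#' @param group_a,group_b disjoint, non-empty vectors of biosample row
#'   indices or ids.
#' @param x optional [annotation_matrix] used to resolve ids to indices.
#' @return An object of class `group_pair` with integer index vectors
#'   `group_a`, `group_b`.
#' @export
group_pair <- function(group_a, group_b, x = NULL) {
  resolve <- function(g) {
    if (is.character(g)) {
      if (is.null(x)) stop("an annotation matrix is needed to resolve ids")
      idx <- match(g, x$biosample_ids)
      if (anyNA(idx)) stop("unknown biosample id: ", g[which(is.na(idx))[1L]])
      idx
    } else as.integer(g)
  }
  a <- resolve(group_a); b <- resolve(group_b)
  if (length(a) == 0L || length(b) == 0L) stop("groups must be non-empty")
  if (length(intersect(a, b))) stop("groups must be disjoint")
  if (anyDuplicated(a) || anyDuplicated(b)) stop("duplicate group members")
  structure(list(group_a = a, group_b = b), class = "group_pair")
}

#' Joint background for a group comparison
#'
#' Expected state frequencies computed from the pooled biosamples of both
#' groups, ensuring a consistent background for the two groups' saliency
#' profiles.
#'
#' @param x an [annotation_matrix].
#' @param pair a [group_pair].
#' @param pseudocount as in [expected_frequencies].
#' @return A `state_background` with `q`.
#' @export
joint_background <- function(x, pair, pseudocount = 0) {
  stopifnot(inherits(x, "annotation_matrix"), inherits(pair, "group_pair"))
  rows <- c(pair$group_a, pair$group_b)
  if (max(rows) > nrow(x$states)) stop("group index out of range")
  n <- x$model$n_states
  cnt <- tabulate(x$states[rows, , drop = FALSE], nbins = n) + pseudocount
  .state_background(q = cnt / sum(cnt))
}

# Signed SSED for an arbitrary row split, against a fixed joint background.
# Returns list(ssed, state_contrib) where state_contrib is B x n of
# (sA_i - sB_i)^2, or only ssed when contrib = FALSE.
.ssed_core <- function(states, rows_a, rows_b, q, n, contrib = FALSE) {
  B <- ncol(states)
  pa <- state_counts(states, n, rows_a) / length(rows_a)
  pb <- state_counts(states, n, rows_b) / length(rows_b)
  sa <- matrix(0, n, B)
  sb <- matrix(0, n, B)
  for (i in seq_len(n)) {
    sa[i, ] <- .plogpq(pa[i, ], rep(q[i], B), "state")
    sb[i, ] <- .plogpq(pb[i, ], rep(q[i], B), "state")
  }
  diff2 <- (sa - sb)^2
  d2 <- colSums(diff2)
  sgn <- ifelse(colSums(sa) >= colSums(sb), 1, -1)  # exact tie -> positive
  if (contrib) list(ssed = sgn * d2, state_contrib = t(diff2))
  else list(ssed = sgn * d2)
}

#' Signed squared Euclidean distance between two groups' saliency profiles
#'
#' At each bin, both groups' per-state saliency vectors are computed against
#' the joint background (pooled over both groups), and their squared
#' Euclidean distance is reported, signed positive when group A has the
#' higher total saliency and negative otherwise (an exact tie with nonzero
#' distance is signed positive). Bins at which every biosample of both
#' groups carries the designated quiescent state are flagged `excluded`;
#' they are ignored when fitting the permutation null.
#'
#' @param x an [annotation_matrix].
#' @param pair a [group_pair].
#' @param background optional `state_background` (joint); computed from the
#'   pooled groups when `NULL`.
#' @return An object of class `differential_track`: `ssed` (per bin),
#'   `state_contrib` (`B x n` per-state squared differences, for region
#'   labeling), `excluded` (logical per bin), `pvalue`/`qvalue`/`fit`
#'   (`NULL` until filled), `bins`, `model`, `pair`.
#' @export
ssed_scores <- function(x, pair, background = NULL) {
  stopifnot(inherits(x, "annotation_matrix"), inherits(pair, "group_pair"))
  if (is.null(background)) background <- joint_background(x, pair)
  q <- background$q
  n <- x$model$n_states
  core <- .ssed_core(x$states, pair$group_a, pair$group_b, q, n,
                     contrib = TRUE)
  qi <- x$model$quiescent_index
  rows <- c(pair$group_a, pair$group_b)
  excluded <- if (is.na(qi)) rep(FALSE, ncol(x$states))
              else colSums(x$states[rows, , drop = FALSE] != qi) == 0L
  structure(
    list(ssed = core$ssed, state_contrib = core$state_contrib,
         excluded = excluded, pvalue = NULL, qvalue = NULL, fit = NULL,
         bins = x$bins, model = x$model, pair = pair,
         background = background),
    class = "differential_track"
  )
}

#' @export
print.differential_track <- function(x, ...) {
  cat("differential_track:", length(x$ssed), "bins;",
      sum(x$excluded), "all-quiescent bins excluded\n")
  if (!is.null(x$fit)) print(x$fit)
  if (!is.null(x$qvalue))
    cat("  bins with q < 0.05:", sum(x$qvalue < 0.05), "\n")
  invisible(x)
}

#' Permutation null for the differential statistic
#'
#' Repeatedly permutes the biosample group labels (preserving the original
#' group sizes), recomputes the signed statistic genome-wide against the
#' unchanged joint background, and pools the permuted values, excluding
#' all-quiescent bins. From the pool it repeatedly draws subsamples of
#' `sample_size` bins (default 100,000), fits the generalized normal to
#' each by maximum likelihood, and returns the fit with the median negative
#' log-likelihood (the lower median for an even number of fits).
#'
#' @param x an [annotation_matrix].
#' @param pair a [group_pair].
#' @param n_perms number of label permutations (default 100).
#' @param sample_size bins per fitting subsample (default 100000).
#' @param n_fits number of repeated subsample fits (default 11, odd so the
#'   median is a single fit).
#' @param seed integer seed driving both the permutations and the
#'   subsampling; `NULL` leaves the RNG state alone.
#' @param background optional joint `state_background`.
#' @return A `gnorm_fit`.
#' @export
permutation_null <- function(x, pair, n_perms = 100L, sample_size = 100000L,
                             n_fits = 11L, seed = NULL, background = NULL) {
  stopifnot(inherits(x, "annotation_matrix"), inherits(pair, "group_pair"),
            n_perms >= 1L, sample_size >= 100L, n_fits >= 1L)
  rows <- c(pair$group_a, pair$group_b)
  ma <- length(pair$group_a)
  if (choose(length(rows), ma) < 2)
    stop("fewer than 2 distinct group assignments are possible")
  if (is.na(x$model$quiescent_index))
    warning("no quiescent state designated; all-quiescent exclusion skipped")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(background)) background <- joint_background(x, pair)
  q <- background$q
  n <- x$model$n_states
  qi <- x$model$quiescent_index
  keep <- if (is.na(qi)) rep(TRUE, ncol(x$states))
          else colSums(x$states[rows, , drop = FALSE] != qi) > 0L
  if (!any(keep)) stop("every bin is all-quiescent; nothing to fit")

  pool <- vector("list", n_perms)
  for (p in seq_len(n_perms)) {
    perm <- sample(rows)
    core <- .ssed_core(x$states, perm[seq_len(ma)], perm[-seq_len(ma)], q, n)
    pool[[p]] <- core$ssed[keep]
  }
  pool <- unlist(pool, use.names = FALSE)
  take <- min(sample_size, length(pool))
  fits <- vector("list", n_fits)
  for (f in seq_len(n_fits))
    fits[[f]] <- fit_gnorm(pool[sample.int(length(pool), take)])
  nlls <- vapply(fits, `[[`, numeric(1L), "nll")
  med <- order(nlls)[ceiling(length(nlls) / 2)]  # lower median when even
  fits[[med]]
}

#' Empirical p-values from a fitted null
#'
#' Two-sided: `p = P(|X - loc| >= |ssed - loc|)` under the fitted
#' generalized normal. Excluded (all-quiescent) bins receive `p = 1`.
#'
#' @param track a [ssed_scores] result.
#' @param fit a `gnorm_fit` (e.g. from [permutation_null]).
#' @return The track with `pvalue` and `fit` filled.
#' @export
empirical_pvalues <- function(track, fit) {
  stopifnot(inherits(track, "differential_track"), inherits(fit, "gnorm_fit"))
  p <- pgnorm_two_sided(track$ssed, fit$loc, fit$scale, fit$shape)
  p[track$excluded] <- 1
  track$pvalue <- p
  track$fit <- fit
  track
}

#' Benjamini-Hochberg adjustment over non-excluded bins
#'
#' Standard step-up false-discovery-rate control applied to the
#' non-excluded bins only; excluded bins are assigned an adjusted value
#' of 1.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @param exclude_mask logical vector flagging bins to leave out.
#' @return Vector of adjusted values, same length as `pvalues`.
#' @export
bh_fdr <- function(pvalues, exclude_mask = NULL) {
  if (is.null(exclude_mask)) exclude_mask <- rep(FALSE, length(pvalues))
  stopifnot(length(exclude_mask) == length(pvalues),
            all(pvalues >= 0 & pvalues <= 1))
  out <- rep(1, length(pvalues))
  out[!exclude_mask] <- stats::p.adjust(pvalues[!exclude_mask],
                                        method = "BH")
  out
}

#' Adjust a differential track for multiple testing
#'
#' @param track a [differential_track] with p-values filled.
#' @return The track with `qvalue` filled via [bh_fdr].
#' @export
adjust_fdr <- function(track) {
  stopifnot(inherits(track, "differential_track"),
            !is.null(track$pvalue))
  track$qvalue <- bh_fdr(track$pvalue, track$excluded)
  track
}

#' Full pairwise differential analysis
#'
#' Convenience wrapper: signed statistic, permutation null, p-values, FDR.
#'
#' @inheritParams permutation_null
#' @return A [differential_track] with `pvalue`, `qvalue` and `fit` filled.
#' @export
pairwise_analysis <- function(x, pair, n_perms = 100L,
                              sample_size = 100000L, n_fits = 11L,
                              seed = NULL) {
  background <- joint_background(x, pair)
  track <- ssed_scores(x, pair, background)
  fit <- permutation_null(x, pair, n_perms = n_perms,
                          sample_size = sample_size, n_fits = n_fits,
                          seed = seed, background = background)
  adjust_fdr(empirical_pvalues(track, fit))
}

#' Top differential regions between two groups
#'
#' Runs the greedy region recommendation on the magnitude of the signed
#' statistic and annotates each region with its signed aggregate, the
#' direction (which group is more salient) and the state contributing most
#' to the squared distance within the region.
#'
#' @param track a [differential_track].
#' @param region_size region width in bp (default 25000, the pairwise
#'   default).
#' @param k maximum number of regions (default 100).
#' @return A [region_set] with provenance `"differential"` and extra
#'   columns `signed_score`, `direction` (`"A"`/`"B"`), `top_state`.
#' @export
top_differential_regions <- function(track, region_size = 25000L, k = 100L) {
  stopifnot(inherits(track, "differential_track"))
  rs <- recommend_regions(abs(track$ssed), track$bins,
                          region_size = region_size, k = k)
  tab <- rs$regions
  if (nrow(tab) > 0L) {
    signed <- numeric(nrow(tab))
    direction <- character(nrow(tab))
    top_state <- character(nrow(tab))
    for (r in seq_len(nrow(tab))) {
      idx <- bin_index(track$bins, tab$chrom[r],
                       seq(tab$start[r], tab$end[r] - 1L,
                           by = track$bins$bin_size))
      signed[r] <- sum(track$ssed[idx])
      direction[r] <- if (signed[r] >= 0) "A" else "B"
      contrib <- colSums(track$state_contrib[idx, , drop = FALSE])
      top_state[r] <- track$model$labels[which.max(contrib)]
    }
    tab$signed_score <- signed
    tab$direction <- direction
    tab$top_state <- top_state
  }
  region_set(tab, provenance = "differential")
}
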