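#' Genome-wide background of state frequencies
#'
#' Background (expected) frequencies are the null model of the saliency
#' scores: `q_i` is the genome-wide frequency of state `i` over all
#' (biosample, bin) entries. Backgrounds are computed over all bins,
#' including all-quiescent ones.
#'
#' @param x an [annotation_matrix].
#' @param pseudocount nonnegative count added to each state's tally before
#'   normalization (default 0). Useful when scoring one dataset against a
#'   background derived from another, to guard against `log(p/0)`.
#' @return An object of class `state_background` with field `q` (length-n,
#'   sums to 1); `pair_q` and `pair_sample_q` are `NULL` until filled by
#'   [expected_pair_frequencies] / [expected_pair_sample_frequencies].
#' @export
#' @examples
#' m <- annotation_matrix(rbind(c(1, 1, 2, 2), c(1, 2, 2, 2)),
#'                        c("a", "b"), genome_bins(c(chr1 = 4)),
#'                        state_model(c("A", "B")))
#' expected_frequencies(m)$q  # 3/8, 5/8
expected_frequencies <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "annotation_matrix"), pseudocount >= 0)
  n <- x$model$n_states
  cnt <- tabulate(x$states, nbins = n) + pseudocount
  .state_background(q = cnt / sum(cnt))
}

.state_background <- function(q = NULL, pair_q = NULL, pair_sample_q = NULL) {
  structure(list(q = q, pair_q = pair_q, pair_sample_q = pair_sample_q),
            class = "state_background")
}

#' Observed state frequencies at one bin
#'
#' `p_i` is the fraction of biosamples carrying state `i` at the bin.
#'
#' @param x an [annotation_matrix].
#' @param bin 1-based global bin index.
#' @return Length-n frequency vector summing to 1.
#' @export
observed_frequencies <- function(x, bin) {
  stopifnot(inherits(x, "annotation_matrix"))
  bin <- as.integer(bin)
  if (bin < 1L || bin > x$bins$total_bins) stop("bin index out of range")
  tabulate(x$states[, bin], nbins = x$model$n_states) / nrow(x$states)
}

#' Construct a score track
#'
#' @param per_state `total_bins x n_states` matrix of per-state saliency
#'   levels in bits.
#' @param bins a [genome_bins].
#' @param model a [state_model].
#' @param metric one of `"S1"`, `"S2"`, `"S3"`.
#' @return An object of class `score_track` with fields `per_state`, `total`
#'   (row sums), `metric`, `bins`, `model`.
#' @export
score_track <- function(per_state, bins, model, metric = c("S1", "S2", "S3")) {
  stopifnot(inherits(bins, "genome_bins"), inherits(model, "state_model"))
  metric <- match.arg(metric)
  per_state <- as.matrix(per_state)
  if (nrow(per_state) != bins$total_bins || ncol(per_state) != model$n_states)
    stop("per_state must be total_bins x n_states")
  structure(
    list(per_state = per_state, total = rowSums(per_state), metric = metric,
         bins = bins, model = model),
    class = "score_track"
  )
}

#' @export
print.score_track <- function(x, ...) {
  cat("score_track (", x$metric, "): ", x$bins$total_bins, " bins, ",
      x$model$n_states, " states; total saliency range [",
      signif(min(x$total), 4L), ", ", signif(max(x$total), 4L), "] bits\n",
      sep = "")
  invisible(x)
}

# p * log2(p / q) with the KL convention 0 * log2(0/q) = 0; errors when
# p > 0 meets q = 0.
.plogpq <- function(p, q, what) {
  out <- numeric(length(p))
  pos <- p > 0
  if (any(pos & q == 0))
    stop("background frequency is zero for an observed ", what,
         "; use a pseudocount")
  out[pos] <- p[pos] * log2(p[pos] / q[pos])
  out
}

#' Basic saliency: relative entropy against genome-wide state frequencies
#'
#' The per-state level at a bin is `p_i * log2(p_i / q_i)` — the
#' contribution of state `i` to the Kullback-Leibler divergence between the
#' bin's observed state distribution `p` (across biosamples) and the
#' genome-wide background `q`. The per-bin total is `KL(p || q) >= 0` when
#' the background derives from the same matrix; individual per-state
#' levels may be negative and are retained unclipped. Rare states receive
#' larger weight per observation, so regulatory states (enhancers,
#' promoters) are upweighted relative to quiescent or broadly transcribed
#' chromatin.
#'
#' @param x an [annotation_matrix].
#' @param background a `state_background` with `q`, or `NULL` to compute it
#'   from `x`.
#' @return A [score_track] with metric `"S1"`.
#' @export
s1_scores <- function(x, background = NULL) {
  stopifnot(inherits(x, "annotation_matrix"))
  if (is.null(background)) background <- expected_frequencies(x)
  q <- background$q
  n <- x$model$n_states
  if (length(q) != n) stop("background has wrong number of states")
  m <- nrow(x$states)
  p <- state_counts(x) / m                # n x B
  per <- matrix(0, ncol(x$states), n)
  for (i in seq_len(n)) {
    pi <- p[i, ]
    pos <- pi > 0
    if (any(pos) && q[i] == 0)
      stop("state '", x$model$labels[i], "' observed (first at bin ",
           which(pos)[1L], ") but has zero background frequency")
    per[pos, i] <- pi[pos] * log2(pi[pos] / q[i])
  }
  score_track(per, x$bins, x$model, "S1")
}

#' Genome-wide background of state-pair co-occurrence
#'
#' For each bin the distribution over ordered pairs of distinct biosamples
#' assigns `p_ij = #\{(a,b): a != b, state_a = i, state_b = j\} / (m(m-1))`;
#' the pair background `q_ij` is the mean of these per-bin distributions over
#' all bins. Self-pairs are excluded (they carry no co-occurrence
#' information); the result is symmetric and sums to 1.
#'
#' @param x an [annotation_matrix] with at least 2 biosamples.
#' @return A `state_background` with `q` and `pair_q` filled.
#' @export
expected_pair_frequencies <- function(x) {
  stopifnot(inherits(x, "annotation_matrix"))
  m <- nrow(x$states)
  if (m < 2L) stop("pair metrics require at least 2 biosamples")
  cnt <- state_counts(x)                  # n x B
  M <- tcrossprod(cnt)                    # sum over bins of c_i * c_j
  diag(M) <- diag(M) - rowSums(cnt)       # remove self-pairs
  pair_q <- M / (ncol(cnt) * m * (m - 1))
  .state_background(q = expected_frequencies(x)$q, pair_q = pair_q)
}

#' State co-occurrence-adjusted saliency
#'
#' Scores each bin's distribution of ordered state pairs (over distinct
#' biosample pairs) against the genome-wide pair background: the per-state
#' level is `sum_j p_ij log2(p_ij / q_ij)`. This upweights configurations
#' where combinations of states co-occur more often than expected, e.g.
#' enhancer states recurring across biosamples, which are more surprising
#' than ubiquitously shared promoter states.
#'
#' @param x an [annotation_matrix] with `m >= 2`.
#' @param background a `state_background` with `pair_q`, or `NULL` to
#'   compute it from `x`.
#' @return A [score_track] with metric `"S2"`; the per-bin total is the KL
#'   divergence of the bin's pair distribution against `pair_q`, hence
#'   nonnegative under a same-matrix background.
#' @export
s2_scores <- function(x, background = NULL) {
  stopifnot(inherits(x, "annotation_matrix"))
  m <- nrow(x$states)
  if (m < 2L) stop("S2 requires at least 2 biosamples")
  if (is.null(background) || is.null(background$pair_q))
    background <- expected_pair_frequencies(x)
  pq <- background$pair_q
  n <- x$model$n_states
  cnt <- state_counts(x)
  B <- ncol(cnt)
  norm <- m * (m - 1)
  per <- matrix(0, B, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pij <- cnt[i, ] * cnt[j, ]
      if (i == j) pij <- pij - cnt[i, ]
      pij <- pij / norm
      pos <- pij > 0
      if (!any(pos)) next
      if (pq[i, j] == 0)
        stop("state pair (", x$model$labels[i], ", ", x$model$labels[j],
             ") observed but has zero background frequency")
      per[pos, i] <- per[pos, i] + pij[pos] * log2(pij[pos] / pq[i, j])
    }
  }
  score_track(per, x$bins, x$model, "S2")
}

#' Background of state pairs per ordered biosample pair
#'
#' `pair_sample_q[i, j, a, b]` is the fraction of (bin, ordered biosample
#' pair) events in which biosample `a` carries state `i` and biosample `b`
#' carries state `j`, i.e. the genome-wide rate at which each specific
#' biosample pair shares each state pair. Sums to 1 over all
#' `(i, j, a, b)`; marginalizing over `(a, b)` recovers `pair_q`.
#'
#' @param x an [annotation_matrix] with `m >= 2`.
#' @return A `state_background` with `q`, `pair_q` and `pair_sample_q`
#'   (an `n x n x m x m` array, zero on the `a == b` slices) filled.
#' @export
expected_pair_sample_frequencies <- function(x) {
  stopifnot(inherits(x, "annotation_matrix"))
  m <- nrow(x$states)
  if (m < 2L) stop("pair metrics require at least 2 biosamples")
  n <- x$model$n_states
  B <- ncol(x$states)
  q4 <- array(0, c(n, n, m, m))
  denom <- B * m * (m - 1)
  for (a in seq_len(m)) {
    sa <- x$states[a, ]
    for (b in seq_len(m)) {
      if (a == b) next
      joint <- tabulate(sa + n * (x$states[b, ] - 1L), nbins = n * n)
      q4[, , a, b] <- matrix(joint, n, n) / denom
    }
  }
  bg <- expected_pair_frequencies(x)
  .state_background(q = bg$q, pair_q = bg$pair_q, pair_sample_q = q4)
}

#' State- and biosample-pair-adjusted saliency
#'
#' Extends the pair metric with biosample identity: each bin's joint
#' distribution over (state of biosample a, state of biosample b, a, b) is
#' scored against the genome-wide per-biosample-pair background, so state
#' sharing between biosamples that rarely agree is more salient than the
#' same sharing between near-identical biosamples. The computation streams
#' over ordered biosample pairs; no per-bin joint tensor is materialized.
#'
#' @param x an [annotation_matrix] with `m >= 2`.
#' @param background a `state_background` with `pair_sample_q`, or `NULL`
#'   to compute it from `x`.
#' @return A [score_track] with metric `"S3"`; per-bin totals are KL
#'   divergences, nonnegative under a same-matrix background.
#' @export
s3_scores <- function(x, background = NULL) {
  stopifnot(inherits(x, "annotation_matrix"))
  m <- nrow(x$states)
  if (m < 2L) stop("S3 requires at least 2 biosamples")
  if (is.null(background) || is.null(background$pair_sample_q))
    background <- expected_pair_sample_frequencies(x)
  q4 <- background$pair_sample_q
  n <- x$model$n_states
  B <- ncol(x$states)
  w <- 1 / (m * (m - 1))
  lw <- log2(w)
  per <- matrix(0, B, n)
  binseq <- seq_len(B)
  for (a in seq_len(m)) {
    sa <- x$states[a, ]
    for (b in seq_len(m)) {
      if (a == b) next
      sb <- x$states[b, ]
      qv <- q4[cbind(sa, sb, a, b)]
      if (any(qv == 0))
        stop("observed (state, state, biosample, biosample) event has zero ",
             "background frequency; use a same-matrix background")
      idx <- cbind(binseq, sa)            # bin indices unique within a pair
      per[idx] <- per[idx] + w * (lw - log2(qv))
    }
  }
  score_track(per, x$bins, x$model, "S3")
}

#' Consensus epigenome: most salient state per bin
#'
#' Selects at each bin the state with the maximal per-state saliency level,
#' collapsing the multi-biosample annotation into a single consensus track.
#' Unlike the per-bin dominant (most frequent) state, the consensus
#' upweights rare, information-rich states, so regulatory states are
#' over-represented relative to quiescent chromatin.
#'
#' @param scores a [score_track].
#' @return Integer vector of state indices, one per bin; ties are broken
#'   toward the lowest state index (reported via a message when present).
#' @export
consensus_states <- function(scores) {
  stopifnot(inherits(scores, "score_track"))
  cons <- max.col(scores$per_state, ties.method = "first")
  rowmax <- scores$per_state[cbind(seq_along(cons), cons)]
  nties <- sum(rowSums(scores$per_state == rowmax) > 1L)
  if (nties > 0L)
    message(nties, " bin(s) had tied maximal saliency; lowest state index kept")
  cons
}

#' Dominant state per bin
#'
#' The most frequent state across biosamples at each bin (plurality vote),
#' the natural contrast to [consensus_states].
#'
#' @param x an [annotation_matrix].
#' @return Integer vector of state indices; ties toward the lowest index.
#' @export
dominant_states <- function(x) {
  stopifnot(inherits(x, "annotation_matrix"))
  max.col(t(state_counts(x)), ties.method = "first")
}
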