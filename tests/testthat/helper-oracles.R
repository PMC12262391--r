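# Brute-force reference implementations, written directly from the score
# definitions with plain loops. They stay deliberately independent of the
# package's vectorized code paths.

# Relative-entropy saliency per bin and state: p_i * log2(p_i / q_i).
oracle_s1 <- function(states, n, q = NULL) {
  m <- nrow(states); B <- ncol(states)
  if (is.null(q)) q <- tabulate(states, n) / (m * B)
  per <- matrix(0, B, n)
  for (b in seq_len(B)) {
    for (i in seq_len(n)) {
      p <- sum(states[, b] == i) / m
      if (p > 0) per[b, i] <- p * log2(p / q[i])
    }
  }
  per
}

# Per-bin distribution over ordered distinct biosample pairs.
oracle_pair_dist <- function(col, n) {
  m <- length(col)
  p <- matrix(0, n, n)
  for (a in seq_len(m)) for (b in seq_len(m)) if (a != b)
    p[col[a], col[b]] <- p[col[a], col[b]] + 1
  p / (m * (m - 1))
}

oracle_pair_q <- function(states, n) {
  B <- ncol(states)
  q <- matrix(0, n, n)
  for (b in seq_len(B)) q <- q + oracle_pair_dist(states[, b], n)
  q / B
}

oracle_s2 <- function(states, n, pair_q = NULL) {
  B <- ncol(states)
  if (is.null(pair_q)) pair_q <- oracle_pair_q(states, n)
  per <- matrix(0, B, n)
  for (b in seq_len(B)) {
    p <- oracle_pair_dist(states[, b], n)
    for (i in seq_len(n)) for (j in seq_len(n))
      if (p[i, j] > 0)
        per[b, i] <- per[b, i] + p[i, j] * log2(p[i, j] / pair_q[i, j])
  }
  per
}

oracle_pair_sample_q <- function(states, n) {
  m <- nrow(states); B <- ncol(states)
  q <- array(0, c(n, n, m, m))
  for (b in seq_len(B))
    for (a in seq_len(m)) for (bb in seq_len(m)) if (a != bb)
      q[states[a, b], states[bb, b], a, bb] <-
        q[states[a, b], states[bb, b], a, bb] + 1
  q / (B * m * (m - 1))
}

oracle_s3 <- function(states, n, q4 = NULL) {
  m <- nrow(states); B <- ncol(states)
  if (is.null(q4)) q4 <- oracle_pair_sample_q(states, n)
  w <- 1 / (m * (m - 1))
  per <- matrix(0, B, n)
  for (b in seq_len(B))
    for (a in seq_len(m)) for (bb in seq_len(m)) if (a != bb) {
      i <- states[a, b]; j <- states[bb, b]
      per[b, i] <- per[b, i] + w * log2(w / q4[i, j, a, bb])
    }
  per
}

# Exhaustive maximum-sum window of w bins over a single-chromosome score
# vector; returns list(start_bin, sum).
oracle_max_window <- function(scores, w) {
  best <- -Inf; at <- NA_integer_
  for (s in seq_len(length(scores) - w + 1L)) {
    tot <- sum(scores[s:(s + w - 1L)])
    if (tot > best) { best <- tot; at <- s }
  }
  list(start_bin = at, sum = best)
}

# Brute-force per-state max pooling of a (25c x n) score block into 25 rows.
oracle_pool <- function(sub, c) {
  out <- matrix(0, 25L, ncol(sub))
  for (blk in seq_len(25L)) {
    rows <- ((blk - 1L) * c + 1L):(blk * c)
    for (i in seq_len(ncol(sub))) out[blk, i] <- max(sub[rows, i])
  }
  out
}
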