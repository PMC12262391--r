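# Build an annotation matrix from a bare integer matrix on one chromosome.
make_matrix <- function(states, n_states = max(states), quiescent = NULL,
                        bin_size = 200L) {
  states <- as.matrix(states)
  annotation_matrix(
    states,
    sprintf("bs%d", seq_len(nrow(states))),
    genome_bins(c(chr1 = ncol(states)), bin_size),
    state_model(sprintf("E%d", seq_len(n_states)), quiescent = quiescent)
  )
}

# Random annotation matrix for property-style loops.
random_matrix <- function(m, B, n, seed) {
  set.seed(seed)
  make_matrix(matrix(sample.int(n, m * B, replace = TRUE), m), n_states = n)
}

# A quiescent-dominated state frequency profile: the designated quiescent
# state (last) holds `quiescent_mass`; the remaining mass decays
# geometrically over the other states, mimicking the rarity gradient from
# broadly transcribed down to enhancer/promoter states.
realistic_freqs <- function(n_states, quiescent_mass = 0.7) {
  w <- 0.7^seq_len(n_states - 1L)
  c(w / sum(w) * (1 - quiescent_mass), quiescent_mass)
}
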