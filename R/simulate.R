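#' Specify a synthetic annotation dataset
#'
#' Describes a categorical annotation matrix to generate: background state
#' labels drawn i.i.d. per (biosample, bin) from target genome-wide
#' frequencies (optionally with geometric run lengths, which better mimics
#' the segment-length structure of real ChromHMM tracks), plus planted
#' features that overwrite their bins deterministically. The same seed
#' always yields the same matrix.
#'
#' @param n_states number of chromatin states.
#' @param m_biosamples number of biosamples (matrix rows).
#' @param n_bins number of genomic bins (single chromosome `"chr1"` by
#'   default).
#' @param bin_size bin width in bp (default 200).
#' @param state_freqs target genome-wide state frequencies (sums to 1;
#'   default uniform). Real chromatin-state genomes are dominated by the
#'   quiescent state, so a realistic choice puts most mass there.
#' @param seed integer RNG seed.
#' @param quiescent index of the designated quiescent state (default the
#'   last state, the ChromHMM convention; `NA` for none).
#' @param mean_run_length mean geometric run length in bins for the
#'   run-structured background mode, or `NULL` (default) for i.i.d. bins.
#' @param chrom chromosome name.
#' @param model optional [state_model]; default labels are `"E1".."En"`.
#' @return An object of class `simulation_spec` (fields as above plus an
#'   initially empty `plants` list).
#' @export
simulation_spec <- function(n_states, m_biosamples, n_bins, bin_size = 200L,
                            state_freqs = rep(1 / n_states, n_states),
                            seed = 1L, quiescent = n_states,
                            mean_run_length = NULL, chrom = "chr1",
                            model = NULL) {
  stopifnot(n_states >= 1L, m_biosamples >= 1L, n_bins >= 1L)
  if (length(state_freqs) != n_states)
    stop("state_freqs must have one entry per state")
  if (abs(sum(state_freqs) - 1) > 1e-9 || any(state_freqs < 0))
    stop("state_freqs must be nonnegative and sum to 1")
  if (is.null(model))
    model <- state_model(sprintf("E%d", seq_len(n_states)),
                         quiescent = if (is.na(quiescent)) NULL
                                     else quiescent)
  stopifnot(inherits(model, "state_model"), model$n_states == n_states)
  structure(
    list(n_states = as.integer(n_states),
         m_biosamples = as.integer(m_biosamples),
         n_bins = as.integer(n_bins), bin_size = as.integer(bin_size),
         state_freqs = state_freqs, seed = as.integer(seed),
         mean_run_length = mean_run_length, chrom = chrom, model = model,
         plants = list()),
    class = "simulation_spec"
  )
}

# bin ranges occupied by a plant, for overlap checking
.plant_ranges <- function(plant) {
  len <- plant$length
  cbind(start = plant$positions, end = plant$positions + len - 1L)
}

.check_plant_overlap <- function(spec, newplant) {
  new <- .plant_ranges(newplant)
  if (max(new[, "end"]) > spec$n_bins || min(new[, "start"]) < 1L)
    stop("planted feature extends outside the genome")
  for (old in spec$plants) {
    o <- .plant_ranges(old)
    for (i in seq_len(nrow(new)))
      if (any(new[i, "start"] <= o[, "end"] & new[i, "end"] >= o[, "start"]))
        stop("planted features overlap")
  }
  invisible(NULL)
}

#' Plant a recurring multi-biosample pattern
#'
#' Adds `n_copies` of the same biosamples-by-bins state pattern at
#' deterministic, non-overlapping positions — either explicitly given or
#' spread evenly across the genome with at least `min_gap` bins between
#' copies. Used to test similarity search: a pattern planted several times
#' should be recovered from any one copy.
#'
#' @param spec a [simulation_spec].
#' @param pattern integer matrix `m_biosamples x L` of state indices.
#' @param n_copies number of copies.
#' @param min_gap minimum separation between copies, in bins.
#' @param positions optional explicit 1-based start bins of the copies
#'   (length `n_copies`), overriding the even spread.
#' @return The spec with the plant appended.
#' @export
plant_recurrent_pattern <- function(spec, pattern, n_copies = 1L,
                                    min_gap = 0L, positions = NULL) {
  stopifnot(inherits(spec, "simulation_spec"), n_copies >= 1L)
  pattern <- as.matrix(pattern)
  if (nrow(pattern) != spec$m_biosamples)
    stop("pattern must have one row per biosample")
  if (min(pattern) < 1L || max(pattern) > spec$n_states)
    stop("pattern references invalid states")
  L <- ncol(pattern)
  if (is.null(positions)) {
    gap <- max(min_gap, (spec$n_bins - n_copies * L) %/% (n_copies + 1L))
    positions <- gap + (seq_len(n_copies) - 1L) * (L + gap) + 1L
  } else {
    positions <- sort(as.integer(positions))
    if (length(positions) != n_copies)
      stop("positions must have one entry per copy")
    if (any(diff(positions) < L + min_gap))
      stop("explicit positions violate min_gap")
  }
  if (positions[n_copies] + L - 1L > spec$n_bins || positions[1L] < 1L)
    stop("not enough space for ", n_copies, " copies with min_gap ", min_gap)
  plant <- list(kind = "recurrent_pattern", positions = positions,
                length = L, pattern = pattern)
  .check_plant_overlap(spec, plant)
  spec$plants[[length(spec$plants) + 1L]] <- plant
  spec
}

#' Plant a group-differential region
#'
#' Within the given bin range, biosamples of group A are set to `state_a`
#' and those of group B to `state_b`; elsewhere both groups share the
#' background process. Used to test pairwise differential analysis.
#'
#' @param spec a [simulation_spec].
#' @param group_a,group_b disjoint biosample row indices covering any
#'   subset of rows.
#' @param start_bin first bin (1-based) of the region.
#' @param n_region_bins region length in bins.
#' @param state_a,state_b state indices assigned to the two groups.
#' @return The spec with the plant appended.
#' @export
plant_group_differential <- function(spec, group_a, group_b, start_bin,
                                     n_region_bins, state_a, state_b) {
  stopifnot(inherits(spec, "simulation_spec"))
  group_a <- as.integer(group_a); group_b <- as.integer(group_b)
  if (length(group_a) == 0L || length(group_b) == 0L ||
      length(intersect(group_a, group_b)) > 0L ||
      max(c(group_a, group_b)) > spec$m_biosamples ||
      min(c(group_a, group_b)) < 1L)
    stop("invalid group split")
  if (state_a < 1L || state_a > spec$n_states ||
      state_b < 1L || state_b > spec$n_states)
    stop("invalid state")
  plant <- list(kind = "group_differential", positions = as.integer(start_bin),
                length = as.integer(n_region_bins),
                group_a = group_a, group_b = group_b,
                state_a = as.integer(state_a), state_b = as.integer(state_b))
  .check_plant_overlap(spec, plant)
  spec$plants[[length(spec$plants) + 1L]] <- plant
  spec
}

#' Plant rare-state islands
#'
#' At each given bin, a fixed subset of biosamples is set to a (typically
#' globally rare) state. Used to demonstrate the consensus-versus-dominant
#' divergence: a rare state carried by a minority of biosamples can be the
#' most salient state while never being the most frequent one.
#'
#' @param spec a [simulation_spec].
#' @param rows biosample row indices carrying the rare state.
#' @param bins_at 1-based bin positions of the islands.
#' @param state the state index planted.
#' @return The spec with the plant appended.
#' @export
plant_rare_state_island <- function(spec, rows, bins_at, state) {
  stopifnot(inherits(spec, "simulation_spec"))
  rows <- as.integer(rows)
  if (length(rows) == 0L || max(rows) > spec$m_biosamples || min(rows) < 1L)
    stop("invalid biosample rows")
  if (state < 1L || state > spec$n_states) stop("invalid state")
  plant <- list(kind = "rare_state_island",
                positions = as.integer(bins_at), length = 1L,
                rows = rows, state = as.integer(state))
  .check_plant_overlap(spec, plant)
  spec$plants[[length(spec$plants) + 1L]] <- plant
  spec
}

#' Generate the annotation matrix a spec describes
#'
#' @param spec a [simulation_spec].
#' @return An [annotation_matrix]; identical across calls with the same
#'   spec (including seed).
#' @export
simulate_matrix <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  m <- spec$m_biosamples; B <- spec$n_bins; n <- spec$n_states
  if (is.null(spec$mean_run_length)) {
    states <- matrix(sample.int(n, m * B, replace = TRUE,
                                prob = spec$state_freqs), nrow = m)
  } else {
    pr <- 1 / spec$mean_run_length
    states <- matrix(0L, m, B)
    for (r in seq_len(m)) {
      filled <- 0L
      while (filled < B) {
        len <- min(stats::rgeom(1L, pr) + 1L, B - filled)
        states[r, filled + seq_len(len)] <-
          sample.int(n, 1L, prob = spec$state_freqs)
        filled <- filled + len
      }
    }
  }
  for (plant in spec$plants) {
    for (pos in plant$positions) {
      span <- pos:(pos + plant$length - 1L)
      switch(plant$kind,
        recurrent_pattern = { states[, span] <- plant$pattern },
        group_differential = {
          states[plant$group_a, span] <- plant$state_a
          states[plant$group_b, span] <- plant$state_b
        },
        rare_state_island = { states[plant$rows, span] <- plant$state }
      )
    }
  }
  bins <- genome_bins(stats::setNames(B, spec$chrom), spec$bin_size)
  annotation_matrix(states, sprintf("sample%02d", seq_len(m)), bins,
                    spec$model)
}

#' Write an annotation matrix as per-biosample BED segmentations
#'
#' Emits one BED4 file per biosample (runs of equal states merged into
#' intervals, coordinates 0-based half-open, labels from the state model),
#' plus the state model as JSON — the on-disk format [read_segmentations]
#' consumes.
#'
#' @param x an [annotation_matrix].
#' @param dir output directory (created if needed).
#' @return Named list with `segmentations` (file paths, one per biosample)
#'   and `state_model` (JSON path).
#' @export
write_segmentations <- function(x, dir) {
  stopifnot(inherits(x, "annotation_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  coords <- bin_coordinates(x$bins)
  paths <- character(nrow(x$states))
  for (r in seq_len(nrow(x$states))) {
    rows <- list()
    for (ch in x$bins$chrom_names) {
      span <- .chrom_spans(x$bins)
      lo <- span[match(ch, x$bins$chrom_names), "lo"]
      hi <- span[match(ch, x$bins$chrom_names), "hi"]
      runs <- rle(x$states[r, lo:hi])
      last <- cumsum(runs$lengths)
      first <- last - runs$lengths + 1L
      rows[[ch]] <- data.table::data.table(
        chrom = ch,
        start = (first - 1L) * x$bins$bin_size,
        end = last * x$bins$bin_size,
        label = x$model$labels[runs$values])
    }
    paths[r] <- file.path(dir, paste0(x$biosample_ids[r], ".bed"))
    data.table::fwrite(data.table::rbindlist(rows), paths[r], sep = "\t",
                       col.names = FALSE)
  }
  model_path <- file.path(dir, "state_model.json")
  write_state_model(x$model, model_path)
  list(segmentations = stats::setNames(paths, x$biosample_ids),
       state_model = model_path)
}
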