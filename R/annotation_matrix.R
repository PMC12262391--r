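#' Construct an annotation matrix
#'
#' The central data container: categorical chromatin-state labels for `m`
#' biosamples at every genomic bin, stored as an `m x total_bins` integer
#' matrix of 1-based state indices into the model's alphabet.
#'
#' @param states integer matrix, biosamples in rows, bins in columns; entries
#'   in `1..model$n_states`.
#' @param biosample_ids character vector of row identifiers.
#' @param bins a [genome_bins] with `total_bins == ncol(states)`.
#' @param model a [state_model].
#' @return An object of class `annotation_matrix`.
#' @export
annotation_matrix <- function(states, biosample_ids, bins, model) {
  stopifnot(inherits(bins, "genome_bins"), inherits(model, "state_model"))
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (nrow(states) < 1L) stop("need at least one biosample")
  if (ncol(states) != bins$total_bins)
    stop("states has ", ncol(states), " columns but bins define ",
         bins$total_bins, " bins")
  if (length(biosample_ids) != nrow(states))
    stop("one biosample id per row required")
  if (anyDuplicated(biosample_ids)) stop("biosample ids must be unique")
  if (anyNA(states)) stop("states contains missing values")
  if (min(states) < 1L || max(states) > model$n_states)
    stop("state indices must lie in 1..", model$n_states)
  structure(
    list(states = states, biosample_ids = as.character(biosample_ids),
         bins = bins, model = model),
    class = "annotation_matrix"
  )
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat("annotation_matrix:", nrow(x$states), "biosamples x",
      ncol(x$states), "bins (", x$model$n_states, "states,",
      x$bins$bin_size, "bp bins )\n")
  invisible(x)
}

#' @export
dim.annotation_matrix <- function(x) dim(x$states)

#' Per-bin state counts
#'
#' Tallies, for every genomic bin, how many biosamples carry each state.
#'
#' @param x an [annotation_matrix], or an integer state matrix.
#' @param n_states number of states (required when `x` is a bare matrix).
#' @param rows optional subset of biosample rows to tally.
#' @return An `n_states x total_bins` numeric matrix of counts.
#' @export
state_counts <- function(x, n_states = NULL, rows = NULL) {
  if (inherits(x, "annotation_matrix")) {
    n_states <- x$model$n_states
    x <- x$states
  }
  if (is.null(n_states)) stop("n_states required for a bare matrix")
  if (!is.null(rows)) x <- x[rows, , drop = FALSE]
  out <- matrix(0, n_states, ncol(x))
  for (s in seq_len(n_states)) out[s, ] <- colSums(x == s)
  out
}
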