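#' Define a chromatin-state alphabet
#'
#' A state model is the alphabet of `n` categorical chromatin states produced
#' by a segmentation model (ChromHMM-style), together with display metadata
#' and an optional designated quiescent state. The quiescent state is the
#' low-signal state that covers most of the genome; it is used as the default
#' fill for uncovered bins and to exclude all-quiescent bins from the
#' differential null fit.
#'
#' @param labels character vector of unique state identifiers, in model order
#'   (e.g. `"1_TssA"`, `"7_Enh"`, `"15_Quies"`).
#' @param abbreviations character vector of short display names, same length
#'   as `labels`. Defaults to `labels`.
#' @param colors character vector of hex color strings, same length as
#'   `labels`, or `NULL`.
#' @param quiescent label, abbreviation or integer index of the designated
#'   quiescent state, or `NULL` if none is designated.
#' @return An object of class `state_model` with fields `n_states`, `labels`,
#'   `abbreviations`, `colors`, `quiescent_index` (`NA` if undesignated).
#' @export
#' @examples
#' sm <- state_model(c("1_TssA", "7_Enh", "15_Quies"), quiescent = "15_Quies")
#' sm$quiescent_index
state_model <- function(labels, abbreviations = labels, colors = NULL,
                        quiescent = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1L) stop("a state model needs at least one state")
  if (anyDuplicated(labels)) stop("state labels must be unique")
  abbreviations <- as.character(abbreviations)
  if (length(abbreviations) != n)
    stop("abbreviations must have one entry per state")
  if (!is.null(colors)) {
    colors <- as.character(colors)
    if (length(colors) != n) stop("colors must have one entry per state")
  }
  qi <- NA_integer_
  if (!is.null(quiescent) && !is.na(quiescent)) {
    if (is.numeric(quiescent)) {
      qi <- as.integer(quiescent)
      if (qi < 1L || qi > n) stop("quiescent index out of range")
    } else {
      qi <- match(as.character(quiescent), labels)
      if (is.na(qi)) qi <- match(as.character(quiescent), abbreviations)
      if (is.na(qi)) stop("quiescent state '", quiescent, "' not in model")
    }
  }
  structure(
    list(n_states = n, labels = labels, abbreviations = abbreviations,
         colors = colors, quiescent_index = qi),
    class = "state_model"
  )
}

#' @export
print.state_model <- function(x, ...) {
  cat("state_model:", x$n_states, "states\n")
  q <- if (is.na(x$quiescent_index)) "none"
       else x$labels[x$quiescent_index]
  cat("  labels:", paste(utils::head(x$labels, 6L), collapse = ", "),
      if (x$n_states > 6L) "..." else "", "\n")
  cat("  quiescent:", q, "\n")
  invisible(x)
}

#' Read a state model from JSON or two-column TSV
#'
#' The JSON dialect has fields `labels` (required), `abbreviations`,
#' `colors` and `quiescent`. The TSV dialect is two tab-separated columns,
#' label then abbreviation, no header; the quiescent state may be supplied
#' via the `quiescent` argument.
#'
#' @param path file path (`.json` or tab-separated text).
#' @param quiescent overrides or supplies the quiescent designation.
#' @return A [state_model].
#' @export
read_state_model <- function(path, quiescent = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(spec$labels)) stop("state model JSON lacks 'labels': ", path)
    q <- if (!is.null(quiescent)) quiescent else spec$quiescent
    state_model(spec$labels,
                abbreviations = if (is.null(spec$abbreviations)) spec$labels
                                else spec$abbreviations,
                colors = spec$colors, quiescent = q)
  } else {
    tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
    if (ncol(tab) < 2L) stop("state model TSV needs two columns: ", path)
    state_model(tab[[1L]], abbreviations = tab[[2L]], quiescent = quiescent)
  }
}

#' Write a state model to JSON
#'
#' @param model a [state_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_state_model <- function(model, path) {
  stopifnot(inherits(model, "state_model"))
  out <- list(labels = model$labels, abbreviations = model$abbreviations)
  if (!is.null(model$colors)) out$colors <- model$colors
  if (!is.na(model$quiescent_index))
    out$quiescent <- model$labels[model$quiescent_index]
  jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# Lookup table mapping the label dialects seen in published ChromHMM outputs
# ("7_Enh", "Enh", "E7", "7") to 1-based state indices. The numeric dialects
# follow the number embedded in a "7_Enh"-style label when present, the
# model position otherwise.
.state_lookup <- function(model) {
  n <- model$n_states
  num <- suppressWarnings(as.integer(sub("^([0-9]+)_.*$", "\\1",
                                         model$labels)))
  num[is.na(num)] <- seq_len(n)[is.na(num)]
  keys <- c(model$labels, model$abbreviations,
            sprintf("E%d", num), as.character(num))
  idx <- rep(seq_len(n), 4L)
  keep <- !duplicated(keys)
  stats::setNames(idx[keep], keys[keep])
}
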