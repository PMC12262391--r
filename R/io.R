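#' Read per-biosample chromatin-state segmentations
#'
#' Reads BED-like files (>= 4 columns: chrom, start, end, state label;
#' 0-based half-open; plain or gzip) as produced by ChromHMM-style
#' segmenters, expands intervals into fixed-width bins, and stacks one row
#' per file into an [annotation_matrix]. The chromosome universe is the
#' union across files, ordered by first appearance starting from the first
#' file. State labels are matched against the model's labels, abbreviations,
#' and the `"E7"` / `"7"` numeric dialects.
#'
#' Interval starts must be multiples of `bin_size`; a file's final interval
#' on a chromosome may end off-grid (a partial terminal bin), in which case
#' it is truncated to the last full bin with a message. Bins not covered by
#' any interval in a file are assigned `fill_state` (default: the model's
#' quiescent state, if designated; otherwise uncovered bins are an error).
#'
#' @param paths character vector of segmentation file paths; row order of
#'   the result follows `paths`. Names, if set, become biosample ids
#'   (default: file names stripped of extensions).
#' @param model a [state_model].
#' @param bin_size bin width in bp (default 200).
#' @param fill_state label or index used for uncovered bins, or `NULL` for
#'   the default policy above.
#' @return An [annotation_matrix].
#' @export
read_segmentations <- function(paths, model, bin_size = 200L,
                               fill_state = NULL) {
  stopifnot(inherits(model, "state_model"), length(paths) >= 1L)
  bin_size <- as.integer(bin_size)
  lookup <- .state_lookup(model)
  ids <- names(paths)
  if (is.null(ids))
    ids <- sub("\\.(bed|txt|tsv)(\\.gz)?$", "", basename(paths))
  fill <- NA_integer_
  if (!is.null(fill_state)) {
    fill <- if (is.numeric(fill_state)) as.integer(fill_state)
            else unname(lookup[as.character(fill_state)])
    if (is.na(fill) || fill < 1L || fill > model$n_states)
      stop("fill_state '", fill_state, "' not in model")
  } else if (!is.na(model$quiescent_index)) {
    fill <- model$quiescent_index
  }

  tabs <- vector("list", length(paths))
  chrom_order <- character()
  chrom_max <- numeric()
  for (f in seq_along(paths)) {
    tab <- data.table::fread(paths[[f]], header = FALSE, sep = "\t",
                             select = 1:4,
                             col.names = c("chrom", "start", "end", "label"),
                             colClasses = list(character = c(1L, 4L)))
    if (nrow(tab) == 0L) stop("empty segmentation file: ", paths[[f]])
    bad <- which(tab$start %% bin_size != 0L)
    if (length(bad))
      stop("interval not aligned to bin_size ", bin_size, " in ",
           paths[[f]], ": ", tab$chrom[bad[1L]], ":", tab$start[bad[1L]],
           "-", tab$end[bad[1L]])
    # off-grid ends are tolerated only for a chromosome's terminal interval
    # (partial final bin, truncated)
    maxend <- tapply(tab$end, tab$chrom, max)
    offgrid <- which(tab$end %% bin_size != 0L)
    if (length(offgrid)) {
      terminal <- tab$end[offgrid] == maxend[tab$chrom[offgrid]]
      if (!all(terminal)) {
        k <- offgrid[which(!terminal)[1L]]
        stop("interval not aligned to bin_size ", bin_size, " in ",
             paths[[f]], ": ", tab$chrom[k], ":", tab$start[k], "-",
             tab$end[k])
      }
      message("truncating ", length(offgrid), " partial terminal bin(s) in ",
              basename(paths[[f]]))
      tab$end[offgrid] <- (tab$end[offgrid] %/% bin_size) * bin_size
      tab <- tab[tab$end > tab$start, ]
    }
    unknown <- setdiff(unique(tab$label), names(lookup))
    if (length(unknown))
      stop("unknown state label '", unknown[1L], "' in ", paths[[f]])
    tab$state <- unname(lookup[tab$label])
    o <- order(match(tab$chrom, unique(tab$chrom)), tab$start)
    tab <- tab[o, ]
    ov <- tab$chrom[-1L] == tab$chrom[-nrow(tab)] &
          tab$start[-1L] < tab$end[-nrow(tab)]
    if (any(ov)) {
      k <- which(ov)[1L] + 1L
      stop("overlapping intervals in ", paths[[f]], " at ", tab$chrom[k],
           ":", tab$start[k])
    }
    for (ch in unique(tab$chrom)) {
      if (!ch %in% chrom_order) {
        chrom_order <- c(chrom_order, ch)
        chrom_max[ch] <- 0
      }
      chrom_max[ch] <- max(chrom_max[ch], maxend[[ch]])
    }
    tabs[[f]] <- tab
  }

  bpc <- stats::setNames(as.integer(chrom_max[chrom_order] %/% bin_size),
                         chrom_order)
  bins <- genome_bins(bpc, bin_size)
  states <- matrix(NA_integer_, length(paths), bins$total_bins)
  for (f in seq_along(tabs)) {
    tab <- tabs[[f]]
    for (ch in unique(tab$chrom)) {
      sub <- tab[tab$chrom == ch, ]
      off <- bins$offsets[[ch]]
      first <- off + sub$start %/% bin_size + 1L
      len <- (sub$end - sub$start) %/% bin_size
      idx <- sequence(len, from = first)
      states[f, idx] <- rep(sub$state, len)
    }
    miss <- is.na(states[f, ])
    if (any(miss)) {
      if (is.na(fill))
        stop(sum(miss), " uncovered bin(s) in ", paths[[f]],
             " and no fill state configured (designate a quiescent state ",
             "or pass fill_state)")
      states[f, miss] <- fill
    }
  }
  annotation_matrix(states, ids, bins, model)
}

#' Write a saliency score track
#'
#' Two formats: `"tsv"` writes one row per bin with `chrom`, `start`, `end`
#' and one column per state (model order), suitable for round-tripping;
#' `"bedgraph"` writes the per-bin total saliency as a 4-column bedGraph,
#' with runs of adjacent equal-valued bins merged by default.
#'
#' @param scores a [score_track].
#' @param path output path.
#' @param format `"tsv"` or `"bedgraph"`.
#' @param merge_adjacent merge equal-valued adjacent bedGraph rows
#'   (default `TRUE`).
#' @param digits decimal places written (default 6).
#' @return `path`, invisibly.
#' @export
write_score_track <- function(scores, path, format = c("tsv", "bedgraph"),
                              merge_adjacent = TRUE, digits = 6L) {
  stopifnot(inherits(scores, "score_track"))
  format <- match.arg(format)
  coords <- bin_coordinates(scores$bins)
  if (format == "tsv") {
    tab <- data.table::data.table(coords)
    vals <- round(scores$per_state, digits)
    colnames(vals) <- scores$model$labels
    tab <- cbind(tab, data.table::as.data.table(vals))
    data.table::fwrite(tab, path, sep = "\t")
  } else {
    val <- round(scores$total, digits)
    if (merge_adjacent) {
      newrun <- c(TRUE, val[-1L] != val[-length(val)] |
                        coords$chrom[-1L] != coords$chrom[-nrow(coords)])
      first <- which(newrun)
      last <- c(first[-1L] - 1L, length(val))
      tab <- data.table::data.table(chrom = coords$chrom[first],
                                    start = coords$start[first],
                                    end = coords$end[last],
                                    value = val[first])
    } else {
      tab <- data.table::data.table(coords, value = val)
    }
    data.table::fwrite(tab, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}

#' Read a TSV score track written by [write_score_track]
#'
#' @param path TSV path.
#' @param model the [state_model] the track was written with.
#' @return A [score_track] (metric recorded as written, if the file carries
#'   no metric the track is tagged `"S1"`).
#' @export
read_score_track <- function(path, model) {
  stopifnot(inherits(model, "state_model"))
  tab <- data.table::fread(path, header = TRUE, sep = "\t")
  need <- c("chrom", "start", "end", model$labels)
  if (!all(need %in% names(tab)))
    stop("score TSV lacks expected columns: ", path)
  chroms <- unique(tab$chrom)
  bin_size <- as.integer(tab$end[1L] - tab$start[1L])
  bpc <- stats::setNames(as.integer(table(factor(tab$chrom, chroms))), chroms)
  bins <- genome_bins(bpc, bin_size)
  per_state <- as.matrix(tab[, model$labels, with = FALSE])
  dimnames(per_state) <- NULL
  score_track(per_state, bins, model, metric = "S1")
}

#' Write a region set as BED6
#'
#' Rows are `chrom start end name score strand`, strand always `"."`,
#' sorted by rank. The name encodes the rank and, when present, the
#' direction and top-state annotations of differential regions.
#'
#' @param regions a [region_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  tab <- regions$regions
  if (nrow(tab) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  tab <- tab[order(tab$rank), , drop = FALSE]
  name <- paste0("rank", tab$rank)
  if (!is.null(tab$direction))
    name <- paste0(name, "_", tab$direction, "_", tab$top_state)
  out <- data.table::data.table(chrom = tab$chrom, start = tab$start,
                                end = tab$end, name = name,
                                score = signif(tab$score, 6L), strand = ".")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
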