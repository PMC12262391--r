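#' Construct a region set
#'
#' @param regions data.frame with columns `chrom`, `start`, `end` (bp,
#'   0-based half-open), `score`, `rank`; extra columns are kept.
#' @param provenance one of `"recommendation"`, `"differential"`,
#'   `"similarity"`.
#' @return An object of class `region_set`.
#' @export
region_set <- function(regions,
                       provenance = c("recommendation", "differential",
                                      "similarity")) {
  provenance <- match.arg(provenance)
  need <- c("chrom", "start", "end", "score", "rank")
  if (!all(need %in% names(regions)))
    stop("regions need columns ", paste(need, collapse = ", "))
  structure(list(regions = as.data.frame(regions), provenance = provenance),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set (", x$provenance, "): ", nrow(x$regions), " region(s)\n",
      sep = "")
  if (nrow(x$regions)) print(utils::head(x$regions, 5L))
  invisible(x)
}

#' @export
length.region_set <- function(x) nrow(x$regions)

#' Greedy recommendation of high-saliency regions
#'
#' Builds a ranked, non-overlapping set of fixed-size windows. Repeatedly
#' the highest-scoring still-available bin is taken as a seed (score ties
#' broken toward the lower coordinate) and grown one bin at a time,
#' extending to whichever side adds the larger score (ties extend right; a
#' chromosome edge or a bin claimed by an earlier region forces the other
#' side), until the window spans `region_size`. The window's bins are then
#' retired. Seeds must have strictly positive score; regions never cross
#' chromosome boundaries. Ranks are assigned by descending aggregate
#' score. The greedy extension is not guaranteed to find the globally
#' maximal-sum window around a seed, but coincides with it on unimodal
#' score profiles.
#'
#' @param total_scores numeric per-bin score vector (e.g. a score track's
#'   `total`, or `abs(ssed)`).
#' @param bins the [genome_bins] the scores are defined on.
#' @param region_size window width in bp; must be a positive multiple of
#'   the bin size (default 10000, the single-group default).
#' @param k maximum number of regions (default 100).
#' @return A [region_set] with provenance `"recommendation"`, ranked by
#'   descending aggregate score.
#' @export
recommend_regions <- function(total_scores, bins, region_size = 10000L,
                              k = 100L) {
  stopifnot(inherits(bins, "genome_bins"),
            length(total_scores) == bins$total_bins, k >= 1L)
  region_size <- as.integer(region_size)
  if (region_size <= 0L || region_size %% bins$bin_size != 0L)
    stop("region_size must be a positive multiple of bin_size ",
         bins$bin_size)
  w <- region_size %/% bins$bin_size
  spans <- .chrom_spans(bins)
  if (all(bins$bins_per_chrom < w))
    stop("region_size exceeds every chromosome length")
  chrom_lo <- rep(spans[, "lo"], bins$bins_per_chrom)
  chrom_hi <- rep(spans[, "hi"], bins$bins_per_chrom)
  chrom_of <- rep(bins$chrom_names, bins$bins_per_chrom)

  avail <- rep(TRUE, bins$total_bins)
  ord <- order(-total_scores, seq_along(total_scores))
  hits <- list()
  for (b in ord) {
    if (length(hits) >= k) break
    if (total_scores[b] <= 0) break      # ord is descending: no seeds left
    if (!avail[b]) next
    lo <- chrom_lo[b]; hi <- chrom_hi[b]
    if (hi - lo + 1L < w) { avail[b] <- FALSE; next }
    L <- R <- b
    ok <- TRUE
    while (R - L + 1L < w) {
      can_l <- L > lo && avail[L - 1L]
      can_r <- R < hi && avail[R + 1L]
      if (can_l && can_r) {
        if (total_scores[L - 1L] > total_scores[R + 1L]) L <- L - 1L
        else R <- R + 1L                 # tie extends right
      } else if (can_r) R <- R + 1L
      else if (can_l) L <- L - 1L
      else { ok <- FALSE; break }        # squeezed between claimed bins
    }
    if (!ok) { avail[b] <- FALSE; next }
    avail[L:R] <- FALSE
    hits[[length(hits) + 1L]] <-
      list(chrom = chrom_of[b], L = L, lo = lo,
           score = sum(total_scores[L:R]))
  }
  if (length(hits) == 0L) {
    return(region_set(data.frame(chrom = character(), start = integer(),
                                 end = integer(), score = numeric(),
                                 rank = integer()),
                      provenance = "recommendation"))
  }
  tab <- data.frame(
    chrom = vapply(hits, `[[`, character(1L), "chrom"),
    start = vapply(hits, function(h) (h$L - h$lo) * bins$bin_size,
                   numeric(1L)),
    score = vapply(hits, `[[`, numeric(1L), "score"),
    stringsAsFactors = FALSE
  )
  tab$end <- tab$start + region_size
  tab <- tab[order(-tab$score, match(tab$chrom, bins$chrom_names),
                   tab$start), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  region_set(tab[, c("chrom", "start", "end", "score", "rank")],
             provenance = "recommendation")
}

#' Scale-normalized block reduction of a region
#'
#' Represents a region of any supported size as exactly 25 blocks: the
#' region's bins are partitioned into 25 consecutive equal groups and each
#' state's block value is the maximum of its per-bin saliency levels over
#' the group (per-state max pooling). Resolution thus scales with region
#' length, and the flattened `25 * n_states` vector is comparable across
#' region sizes.
#'
#' @param scores a [score_track].
#' @param chrom,start,end region coordinates (bp, 0-based half-open); the
#'   length must be a multiple of `25 * bin_size`.
#' @return An object of class `block_vector`: `values` (25 x n matrix),
#'   `region` (list chrom/start/end), `scale` (length in bp).
#' @export
reduce_region <- function(scores, chrom, start, end) {
  stopifnot(inherits(scores, "score_track"))
  len <- end - start
  unit <- 25L * scores$bins$bin_size
  if (len <= 0L || len %% unit != 0L)
    stop("region length must be a positive multiple of 25 * bin_size = ",
         unit, " bp")
  cpb <- len %/% unit                    # bins per block
  idx <- bin_index(scores$bins, chrom,
                   seq(start, end - 1L, by = scores$bins$bin_size))
  sub <- scores$per_state[idx, , drop = FALSE]
  n <- ncol(sub)
  vals <- matrix(0, 25L, n)
  if (cpb == 1L) {
    vals[] <- sub
  } else {
    for (i in seq_len(n))
      vals[, i] <- apply(matrix(sub[, i], nrow = cpb), 2L, max)
  }
  structure(list(values = vals,
                 region = list(chrom = chrom, start = start, end = end),
                 scale = len),
            class = "block_vector")
}

#' Tile the genome into an index of block vectors
#'
#' Reduces every window of `region_size` placed at `stride` intervals along
#' each chromosome (windows overhanging a chromosome end are skipped) for
#' use in similarity search.
#'
#' @param scores a [score_track].
#' @param region_size window size in bp (multiple of `25 * bin_size`).
#' @param stride spacing between window starts in bp, a multiple of the bin
#'   size; default half the window size, rounded down to a bin multiple.
#' @return An object of class `search_index`: `vectors` (windows x
#'   `25 * n_states` matrix of flattened block values), `regions`
#'   (data.frame chrom/start/end), `region_size`, `stride`.
#' @export
build_search_index <- function(scores, region_size, stride = NULL) {
  stopifnot(inherits(scores, "score_track"))
  region_size <- as.integer(region_size)
  if (is.null(stride))
    stride <- (region_size %/% 2L) %/% scores$bins$bin_size *
      scores$bins$bin_size
  stride <- as.integer(stride)
  if (stride <= 0L || stride %% scores$bins$bin_size != 0L)
    stop("stride must be a positive multiple of the bin size")
  bins <- scores$bins
  rows <- list()
  coords <- list()
  for (ch in bins$chrom_names) {
    L <- bins$bins_per_chrom[[ch]] * bins$bin_size
    if (L < region_size) next
    starts <- seq(0L, L - region_size, by = stride)
    for (s in starts) {
      bv <- reduce_region(scores, ch, s, s + region_size)
      rows[[length(rows) + 1L]] <- as.vector(bv$values)
      coords[[length(coords) + 1L]] <-
        data.frame(chrom = ch, start = s, end = s + region_size,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no chromosome can hold a window of ",
                               region_size, " bp")
  structure(list(vectors = do.call(rbind, rows),
                 regions = do.call(rbind, coords),
                 region_size = region_size, stride = stride),
            class = "search_index")
}

# Euclidean distances from a flattened query to every indexed window.
.index_distances <- function(index, qvec) {
  sqrt(rowSums(sweep(index$vectors, 2L, qvec)^2))
}

# Half-mode of a distance distribution: tallest Freedman-Diaconis histogram
# bin (ties -> lower), midpoint / 2. Degenerate spreads collapse to the
# common value / 2.
.half_mode <- function(d) {
  bw <- 2 * stats::IQR(d) / length(d)^(1 / 3)
  if (!is.finite(bw) || bw <= 0 || diff(range(d)) == 0)
    return(stats::median(d) / 2)
  breaks <- seq(min(d), max(d) + bw, by = bw)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
  h$mids[which.max(h$counts)] / 2
}

#' Similarity threshold from the genome-wide distance distribution
#'
#' Half the mode of the distances from the query to every indexed window;
#' only windows more similar than dissimilar to the query (distance below
#' this threshold) count as matches. The mode is estimated as the midpoint
#' of the tallest Freedman-Diaconis histogram bin (ties toward the lower
#' bin). With fewer than 10 indexed windows the mode is unreliable and
#' half the median is used instead, with a warning.
#'
#' @param index a [build_search_index] result.
#' @param query a `block_vector` (or flattened numeric vector of matching
#'   length).
#' @return The distance threshold (scalar).
#' @export
similarity_threshold <- function(index, query) {
  stopifnot(inherits(index, "search_index"))
  qvec <- if (inherits(query, "block_vector")) as.vector(query$values)
          else as.numeric(query)
  d <- .index_distances(index, qvec)
  if (length(d) < 10L) {
    warning("fewer than 10 indexed windows; using median/2 as threshold")
    return(stats::median(d) / 2)
  }
  .half_mode(d)
}

#' Genome-wide similarity search
#'
#' Finds regions whose chromatin-state saliency architecture resembles the
#' query: the query is block-reduced, the genome is tiled into windows of
#' the query's size, and windows are ranked by ascending Euclidean distance
#' between flattened block vectors. Windows overlapping the query are
#' dropped, and only windows with distance strictly below the half-mode
#' threshold (see [similarity_threshold]) are returned. Supported query
#' sizes are multiples of `25 * bin_size` between 5 kb and 100 kb.
#'
#' @param scores a [score_track].
#' @param chrom,start,end query region coordinates.
#' @param max_hits maximum number of matches returned (default 5).
#' @param stride index tiling stride in bp (default half the query size).
#' @param index optional precomputed [build_search_index] at the query's
#'   size, reused instead of re-tiling.
#' @return A [region_set] with provenance `"similarity"`; `score` holds the
#'   Euclidean distance and ranks ascend with distance.
#' @export
similarity_search <- function(scores, chrom, start, end, max_hits = 5L,
                              stride = NULL, index = NULL) {
  stopifnot(inherits(scores, "score_track"))
  len <- end - start
  if (len < 5000L || len > 100000L)
    stop("query size must lie between 5 kb and 100 kb")
  query <- reduce_region(scores, chrom, start, end)
  if (is.null(index)) {
    index <- build_search_index(scores, as.integer(len), stride)
  } else if (index$region_size != len) {
    stop("precomputed index window size differs from the query size")
  }
  qvec <- as.vector(query$values)
  d <- .index_distances(index, qvec)
  thr <- if (length(d) < 10L) {
    warning("fewer than 10 indexed windows; using median/2 as threshold")
    stats::median(d) / 2
  } else .half_mode(d)
  overlaps <- index$regions$chrom == chrom &
    index$regions$start < end & index$regions$end > start
  keep <- which(!overlaps & d < thr)
  keep <- keep[order(d[keep], index$regions$start[keep])]
  keep <- utils::head(keep, max_hits)
  tab <- index$regions[keep, , drop = FALSE]
  tab$score <- d[keep]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  region_set(tab, provenance = "similarity")
}
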