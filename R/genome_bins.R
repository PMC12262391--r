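#' Define a binned genome coordinate system
#'
#' The genome is partitioned into fixed-width bins (default 200 bp, the
#' nucleosome-scale resolution of ChromHMM segmentations). Bins are indexed
#' globally 1..total_bins, concatenating chromosomes in the stated order;
#' bin b (0-based within its chromosome) covers `[b*bin_size, (b+1)*bin_size)`
#' in 0-based half-open (BED) convention.
#'
#' @param bins_per_chrom named integer vector: bins per chromosome, names are
#'   chromosome identifiers in the desired order.
#' @param bin_size bin width in base pairs (default 200).
#' @return An object of class `genome_bins` with fields `chrom_names`,
#'   `bin_size`, `bins_per_chrom`, `total_bins`, and `offsets` (0-based global
#'   bin offset of each chromosome).
#' @export
#' @examples
#' gb <- genome_bins(c(chr1 = 50, chr2 = 30))
#' gb$total_bins
genome_bins <- function(bins_per_chrom, bin_size = 200L) {
  bin_size <- as.integer(bin_size)
  if (is.na(bin_size) || bin_size <= 0L) stop("bin_size must be positive")
  if (is.null(names(bins_per_chrom)) || any(names(bins_per_chrom) == ""))
    stop("bins_per_chrom must be named by chromosome")
  if (anyDuplicated(names(bins_per_chrom)))
    stop("duplicate chromosome names")
  bpc <- as.integer(bins_per_chrom)
  if (any(is.na(bpc) | bpc < 1L)) stop("each chromosome needs >= 1 bin")
  names(bpc) <- names(bins_per_chrom)
  structure(
    list(chrom_names = names(bpc), bin_size = bin_size, bins_per_chrom = bpc,
         total_bins = sum(bpc),
         offsets = stats::setNames(cumsum(c(0L, bpc[-length(bpc)])),
                                   names(bpc))),
    class = "genome_bins"
  )
}

#' @export
print.genome_bins <- function(x, ...) {
  cat("genome_bins:", x$total_bins, "bins of", x$bin_size, "bp over",
      length(x$chrom_names), "chromosome(s)\n")
  invisible(x)
}

#' Coordinates of every bin
#'
#' @param bins a [genome_bins].
#' @return A data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per global bin in index order.
#' @export
bin_coordinates <- function(bins) {
  stopifnot(inherits(bins, "genome_bins"))
  chrom <- rep(bins$chrom_names, bins$bins_per_chrom)
  within <- sequence(bins$bins_per_chrom) - 1L
  start <- within * bins$bin_size
  data.frame(chrom = chrom, start = start, end = start + bins$bin_size,
             stringsAsFactors = FALSE)
}

#' Global bin index of a genomic position
#'
#' @param bins a [genome_bins].
#' @param chrom chromosome name.
#' @param pos 0-based base-pair position(s).
#' @return 1-based global bin indices.
#' @export
bin_index <- function(bins, chrom, pos) {
  stopifnot(inherits(bins, "genome_bins"))
  if (!chrom %in% bins$chrom_names) stop("unknown chromosome: ", chrom)
  b <- pos %/% bins$bin_size
  if (any(b < 0L | b >= bins$bins_per_chrom[[chrom]]))
    stop("position outside chromosome ", chrom)
  bins$offsets[[chrom]] + b + 1L
}

# Global index range [lo, hi] of each chromosome, as a 2-column matrix.
.chrom_spans <- function(bins) {
  lo <- bins$offsets + 1L
  hi <- bins$offsets + bins$bins_per_chrom
  cbind(lo = lo, hi = hi)
}
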