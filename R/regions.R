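#' Genomic region on a bin grid
#'
#' A chromosome window with a bin resolution. Coordinates are 0-based,
#' half-open (BED convention): bin \code{k} covers
#' \code{[start + k*resolution, start + (k+1)*resolution)}. \code{start} and
#' \code{end} must be multiples of \code{resolution}; use
#' \code{\link{snap_region}} to snap arbitrary coordinates onto the grid.
#'
#' @param chrom chromosome name.
#' @param start 0-based inclusive start, a multiple of \code{resolution}.
#' @param end exclusive end, a multiple of \code{resolution}.
#' @param resolution bin width in bp.
#' @return An object of class \code{genomic_region} with fields
#'   \code{chrom}, \code{start}, \code{end}, \code{resolution}.
#' @examples
#' genomic_region("chr1", 0, 1e6, 1e4)
#' @export
genomic_region <- function(chrom, start, end, resolution) {
  stopifnot(length(chrom) == 1L, is.character(chrom), nchar(chrom) > 0L)
  start <- as.numeric(start); end <- as.numeric(end)
  resolution <- as.numeric(resolution)
  if (!is.finite(resolution) || resolution <= 0)
    stop("resolution must be a positive number")
  if (!is.finite(start) || !is.finite(end) || start < 0 || start >= end)
    stop("need 0 <= start < end")
  if (start %% resolution != 0 || end %% resolution != 0)
    stop("start and end must be multiples of resolution; see snap_region()")
  structure(
    list(chrom = chrom, start = start, end = end, resolution = resolution),
    class = "genomic_region"
  )
}

#' Snap coordinates to a resolution grid
#'
#' Floors \code{start} and ceils \code{end} to multiples of
#' \code{resolution} and returns the snapped \code{\link{genomic_region}}.
#' Readers snap internally and report the snapped region rather than using
#' it silently.
#'
#' @inheritParams genomic_region
#' @return A \code{genomic_region} on the grid.
#' @export
snap_region <- function(chrom, start, end, resolution) {
  resolution <- as.numeric(resolution)
  s <- floor(as.numeric(start) / resolution) * resolution
  e <- ceiling(as.numeric(end) / resolution) * resolution
  if (e == s) e <- s + resolution
  genomic_region(chrom, s, e, resolution)
}

#' Number of bins in a region
#' @param region a \code{genomic_region}.
#' @return integer bin count.
#' @export
n_bins <- function(region) {
  stopifnot(inherits(region, "genomic_region"))
  as.integer((region$end - region$start) / region$resolution)
}

#' Bin start coordinates of a region
#' @param region a \code{genomic_region}.
#' @return numeric vector of 0-based bin starts.
#' @export
bin_starts <- function(region) {
  region$start + (seq_len(n_bins(region)) - 1) * region$resolution
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("<genomic_region> %s:%s-%s @ %s bp (%d bins)\n",
              x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE),
              format(x$resolution, scientific = FALSE), n_bins(x)))
  invisible(x)
}

#' @export
format.genomic_region <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom, format(x$start, scientific = FALSE),
          format(x$end, scientific = FALSE))
}

same_region <- function(a, b) {
  a$chrom == b$chrom && a$start == b$start && a$end == b$end &&
    a$resolution == b$resolution
}

#' Parse a region string
#'
#' Parses \code{"chrom:start-end"} (0-based half-open; commas and
#' underscores in numbers are ignored) and snaps it to \code{resolution}.
#'
#' @param text region string such as \code{"chr1:0-1000000"}.
#' @param resolution bin width in bp.
#' @return A snapped \code{genomic_region}.
#' @export
parse_region <- function(text, resolution) {
  m <- regmatches(text, regexec("^([^:]+):([0-9,_]+)-([0-9,_]+)$", text))[[1]]
  if (length(m) != 4L)
    stop("bad region syntax '", text, "'; expected chrom:start-end")
  num <- function(s) as.numeric(gsub("[,_]", "", s))
  snap_region(m[2], num(m[3]), num(m[4]), resolution)
}

as_granges_region <- function(region) {
  # 0-based half-open -> 1-based closed for GRanges
  GenomicRanges::GRanges(
    region$chrom,
    IRanges::IRanges(start = region$start + 1, end = region$end)
  )
}
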