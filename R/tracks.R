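#' Per-bin 1D signal over a region
#'
#' Length-\code{n_bins(region)} numeric vector, possibly signed (e.g. a
#' compartment eigenvector) and possibly with missing bins. Unsigned tracks
#' must be nonnegative where non-missing.
#'
#' @param values numeric vector of length \code{n_bins(region)}.
#' @param region a \code{\link{genomic_region}}.
#' @param name track label used in layers and result tables.
#' @param signed whether negative values are meaningful (eigenvector mode).
#' @return An object of class \code{binned_track}.
#' @export
binned_track <- function(values, region, name = "track", signed = FALSE) {
  stopifnot(inherits(region, "genomic_region"))
  values <- as.numeric(values)
  if (length(values) != n_bins(region))
    stop("track has ", length(values), " values but region has ",
         n_bins(region), " bins")
  if (!signed && any(values < 0, na.rm = TRUE))
    stop("unsigned track has negative values; set signed = TRUE")
  structure(list(values = values, region = region, name = name,
                 signed = signed),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> '%s' %s, %d bins%s; %d NA\n",
              x$name, format(x$region), length(x$values),
              if (x$signed) " (signed)" else "", sum(is.na(x$values))))
  invisible(x)
}

# Coverage-weighted mean of (start, end, value) intervals per bin.
# Intervals are 0-based half-open genomic coordinates, already on the
# region's chromosome. Bins with no covered base get `empty`.
bin_intervals <- function(starts, ends, values, region, empty = NA_real_) {
  nb <- n_bins(region)
  res <- region$resolution
  wsum <- numeric(nb)
  cov <- numeric(nb)
  s <- pmax(starts, region$start)
  e <- pmin(ends, region$end)
  keep <- which(e > s)
  for (k in keep) {
    b0 <- floor((s[k] - region$start) / res)      # first bin, 0-based
    b1 <- ceiling((e[k] - region$start) / res) - 1 # last bin
    for (b in b0:b1) {
      lo <- region$start + b * res
      hi <- lo + res
      w <- min(e[k], hi) - max(s[k], lo)
      wsum[b + 1] <- wsum[b + 1] + w * values[k]
      cov[b + 1] <- cov[b + 1] + w
    }
  }
  out <- rep(empty, nb)
  hit <- cov > 0
  out[hit] <- wsum[hit] / cov[hit]
  out
}

read_bedgraph_intervals <- function(source) {
  df <- utils::read.table(source, header = FALSE, sep = "",
                          comment.char = "#",
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (nrow(df) == 0) stop("empty bedGraph: ", source)
  if (any(df$end <= df$start))
    stop("malformed bedGraph: interval with end <= start in ", source)
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (is.unsorted(sub$start, strictly = FALSE) ||
        any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("bedGraph intervals on ", ch,
           " are unsorted or overlapping in ", source)
  }
  df
}

#' Read a 1D track binned onto a region
#'
#' Reads a bigWig or bedGraph file and bins it onto \code{region}'s grid.
#' Each bin value is the coverage-weighted mean of the source intervals
#' overlapping the bin; bins touched by no interval are \code{NA}
#' (a coverage gap is missing data, not zero). bedGraph files must be
#' sorted and non-overlapping per chromosome and may carry negative values
#' (pass \code{signed = TRUE} for eigenvector-style tracks).
#'
#' @param source path to a \code{.bw}/\code{.bigwig} or bedGraph file
#'   (format decided by extension; anything not bigWig is parsed as
#'   bedGraph).
#' @param region a \code{genomic_region}; snapped to its own grid first.
#' @param name track label; defaults to the file name.
#' @param signed whether negative values are meaningful.
#' @return A \code{\link{binned_track}}.
#' @export
read_track <- function(source, region, name = NULL, signed = FALSE) {
  stopifnot(inherits(region, "genomic_region"))
  if (!file.exists(source)) stop("no such file: ", source)
  region <- snap_region(region$chrom, region$start, region$end,
                        region$resolution)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(source))
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("bw", "bigwig")) {
    bwf <- rtracklayer::BigWigFile(source)
    si <- rtracklayer::seqinfo(bwf)
    if (!(region$chrom %in% GenomeInfoDb::seqnames(si)))
      stop("chromosome ", region$chrom, " not in ", source)
    gr <- rtracklayer::import(bwf, which = as_granges_region(region))
    starts <- GenomicRanges::start(gr) - 1
    ends <- GenomicRanges::end(gr)
    vals <- S4Vectors::mcols(gr)$score
  } else {
    df <- read_bedgraph_intervals(source)
    if (!(region$chrom %in% df$chrom))
      stop("chromosome ", region$chrom, " not in ", source)
    df <- df[df$chrom == region$chrom, ]
    starts <- df$start; ends <- df$end; vals <- df$value
  }
  v <- bin_intervals(starts, ends, vals, region, empty = NA_real_)
  binned_track(v, region, name = name, signed = signed)
}

#' Convert a BED interval file to a unit-valued track
#'
#' Treats every BED interval as a bedGraph interval with value 1 (a peak
#' file asserts presence), so a bin's value is the fraction of the bin
#' covered by intervals. Bins touched by no interval are 0, not missing: a
#' peak file asserts absence elsewhere.
#'
#' @param source path to a BED3+ file.
#' @param region a \code{genomic_region}.
#' @param name track label; defaults to the file name.
#' @return A \code{\link{binned_track}} with values in [0, 1].
#' @export
bed_to_track <- function(source, region, name = NULL) {
  stopifnot(inherits(region, "genomic_region"))
  if (!file.exists(source)) stop("no such file: ", source)
  region <- snap_region(region$chrom, region$start, region$end,
                        region$resolution)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(source))
  lines <- readLines(source)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  if (length(lines) == 0)
    return(binned_track(numeric(n_bins(region)), region, name = name))
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line (fewer than 3 fields) in ", source)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(start)) || any(is.na(end)) || any(end <= start))
    stop("malformed BED coordinates in ", source)
  keep <- chrom == region$chrom
  v <- bin_intervals(start[keep], end[keep],
                     rep(1, sum(keep)), region, empty = 0)
  # uncovered parts of a partially covered bin count as 0, not gap:
  # recompute as covered-base fraction of the full bin
  if (any(keep)) {
    nbv <- numeric(n_bins(region))
    res <- region$resolution
    s <- pmax(start[keep], region$start)
    e <- pmin(end[keep], region$end)
    ok <- which(e > s)
    for (k in ok) {
      b0 <- floor((s[k] - region$start) / res)
      b1 <- ceiling((e[k] - region$start) / res) - 1
      for (b in b0:b1) {
        lo <- region$start + b * res
        nbv[b + 1] <- nbv[b + 1] + (min(e[k], lo + res) - max(s[k], lo))
      }
    }
    v <- pmin(nbv / res, 1)
  }
  binned_track(v, region, name = name)
}

#' chromHMM segmentation with state colors
#'
#' Labeled, non-overlapping intervals, each carrying an RGB color
#' (BED9 itemRgb). \code{states} records the distinct labels in stable
#' first-seen order with their colors.
#'
#' @param intervals data.frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{state}, and \code{r}, \code{g}, \code{b} in 0-255.
#' @return An object of class \code{chromhmm_segmentation} with fields
#'   \code{intervals} and \code{states} (data.frame \code{state}, \code{r},
#'   \code{g}, \code{b}).
#' @export
chromhmm_segmentation <- function(intervals) {
  need <- c("chrom", "start", "end", "state", "r", "g", "b")
  stopifnot(all(need %in% names(intervals)))
  rgb <- as.matrix(intervals[, c("r", "g", "b")])
  if (any(is.na(rgb)) || any(rgb < 0) || any(rgb > 255))
    stop("RGB components must be in 0-255")
  for (ch in unique(intervals$chrom)) {
    sub <- intervals[intervals$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping segmentation intervals on ", ch)
  }
  first <- !duplicated(intervals$state)
  states <- intervals[first, c("state", "r", "g", "b")]
  rownames(states) <- NULL
  structure(list(intervals = intervals, states = states),
            class = "chromhmm_segmentation")
}

#' @export
print.chromhmm_segmentation <- function(x, ...) {
  cat(sprintf("<chromhmm_segmentation> %d intervals, %d states: %s\n",
              nrow(x$intervals), nrow(x$states),
              paste(x$states$state, collapse = ", ")))
  invisible(x)
}

#' Read a chromHMM BED9 segmentation for a region
#'
#' Parses a BED9 file whose 9th column is an \code{"R,G,B"} itemRgb value,
#' clips intervals to \code{region}, and collects the distinct states in
#' first-seen file order.
#'
#' @param source path to a BED9 file.
#' @param region a \code{genomic_region}.
#' @return A \code{\link{chromhmm_segmentation}}.
#' @export
read_chromhmm <- function(source, region) {
  stopifnot(inherits(region, "genomic_region"))
  if (!file.exists(source)) stop("no such file: ", source)
  region <- snap_region(region$chrom, region$start, region$end,
                        region$resolution)
  lines <- readLines(source)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 9))
    stop("chromHMM file must be BED9 with an itemRgb column: ", source)
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  state <- vapply(fields, `[[`, "", 4L)
  rgbs <- vapply(fields, `[[`, "", 9L)
  parts <- strsplit(rgbs, ",")
  if (any(lengths(parts) != 3))
    stop("unparsable itemRgb field (expected R,G,B) in ", source)
  rgbm <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE))
  if (any(is.na(rgbm)))
    stop("unparsable itemRgb field (non-numeric) in ", source)
  df <- data.frame(chrom = chrom, start = start, end = end, state = state,
                   r = rgbm[, 1], g = rgbm[, 2], b = rgbm[, 3],
                   stringsAsFactors = FALSE)
  df <- df[df$chrom == region$chrom, ]
  df$start <- pmax(df$start, region$start)
  df$end <- pmin(df$end, region$end)
  df <- df[df$end > df$start, ]
  rownames(df) <- NULL
  chromhmm_segmentation(df)
}
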