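#' Contact matrix over a binned region
#'
#' Square symmetric nonnegative matrix of contact frequencies over the bins
#' of a \code{\link{genomic_region}}. Missing bins are \code{NA}, never
#' silently zero. The \code{normalization_tag} records what the values mean:
#' \code{"raw"} counts, \code{"balanced"} (matrix-balanced weights applied),
#' \code{"distnorm"} (observed/expected by diagonal) or \code{"unit-scaled"}
#' (min-max scaled to [0, 1]).
#'
#' @param values square numeric matrix, dimension \code{n_bins(region)}.
#' @param region a \code{genomic_region}.
#' @param normalization_tag one of \code{"raw"}, \code{"balanced"},
#'   \code{"distnorm"}, \code{"unit-scaled"}.
#' @return An object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(values, region, normalization_tag = "raw") {
  stopifnot(inherits(region, "genomic_region"))
  values <- as.matrix(values)
  nb <- n_bins(region)
  if (nrow(values) != nb || ncol(values) != nb)
    stop("matrix is ", nrow(values), "x", ncol(values),
         " but region has ", nb, " bins")
  normalization_tag <- match.arg(normalization_tag,
                                 c("raw", "balanced", "distnorm", "unit-scaled"))
  if (any(values < 0, na.rm = TRUE))
    stop("contact values must be nonnegative")
  ok <- !is.na(values) & !is.na(t(values))
  if (any(abs(values[ok] - t(values)[ok]) >
          1e-6 * (1 + max(abs(values[ok])))))
    stop("contact matrix is not symmetric")
  dimnames(values) <- NULL
  structure(list(values = values, region = region,
                 normalization_tag = normalization_tag),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s, %d x %d, %s; %d NA entries\n",
              format(x$region), nrow(x$values), ncol(x$values),
              x$normalization_tag, sum(is.na(x$values))))
  invisible(x)
}

#' Read a contact matrix for a region
#'
#' Reads the symmetric contact submatrix for \code{region} from either a
#' cooler file (\code{.cool}/\code{.mcool}) or a whitespace-delimited dense
#' text matrix. The requested region is snapped to the stored resolution
#' grid (start floored, end ceiled) and the snapped region is attached to
#' the result. Bins with no data (e.g. unbalanceable bins) are \code{NA}.
#'
#' Dense text sources hold the full matrix for exactly the requested
#' region: the file must be square with \code{n_bins(region)} rows;
#' \code{NA}/\code{nan} entries mark missing bins.
#'
#' @param source path to a \code{.cool}/\code{.mcool} file or a dense text
#'   matrix.
#' @param region a \code{genomic_region}; for cooler sources the resolution
#'   must be stored in the file.
#' @param balance apply stored balancing weights (cooler only). Bins with
#'   no weight become \code{NA}.
#' @return A \code{\link{contact_matrix}} tagged \code{"balanced"} or
#'   \code{"raw"}.
#' @export
read_contact_matrix <- function(source, region, balance = FALSE) {
  stopifnot(inherits(region, "genomic_region"))
  if (!file.exists(source)) stop("no such file: ", source)
  region <- snap_region(region$chrom, region$start, region$end,
                        region$resolution)
  ext <- tolower(tools::file_ext(source))
  if (ext %in% c("cool", "mcool")) {
    read_cooler_matrix(source, region, balance)
  } else {
    vals <- read_dense_matrix(source)
    nb <- n_bins(region)
    if (nrow(vals) != nb)
      stop("dense matrix has ", nrow(vals), " rows but region ",
           format(region), " has ", nb, " bins")
    contact_matrix(vals, region, "raw")
  }
}

read_dense_matrix <- function(path) {
  rows <- utils::read.table(path, header = FALSE,
                            colClasses = "numeric",
                            na.strings = c("NA", "nan", "NaN"))
  vals <- as.matrix(rows)
  if (nrow(vals) != ncol(vals))
    stop("malformed dense matrix (", nrow(vals), " x ", ncol(vals),
         "): not square")
  dimnames(vals) <- NULL
  vals
}

#' Write a contact matrix as dense text
#'
#' Whitespace-delimited square matrix, \code{NA} for missing bins; the
#' round-trip partner of the dense-text branch of
#' \code{\link{read_contact_matrix}}.
#'
#' @param cm a \code{contact_matrix}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_dense_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  utils::write.table(format(cm$values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# ---- cooler (HDF5) via the bundled h5py helper -------------------------

cooler_helper <- function() {
  p <- system.file("python", "cooler_io.py", package = "hicstain")
  if (p == "") stop("bundled cooler helper not found")
  p
}

run_cooler_helper <- function(args) {
  out <- suppressWarnings(
    system2("python", c(shQuote(cooler_helper()), args),
            stdout = TRUE, stderr = TRUE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("cooler helper failed: ", paste(out, collapse = "\n"))
  out
}

read_cooler_matrix <- function(source, region, balance) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  run_cooler_helper(c(
    "dump", shQuote(source), shQuote(region$chrom),
    format(region$start, scientific = FALSE),
    format(region$end, scientific = FALSE),
    format(region$resolution, scientific = FALSE),
    if (balance) "--balance",
    "--out", shQuote(tmp)
  ))
  vals <- read_dense_matrix(tmp)
  contact_matrix(vals, region,
                 if (balance) "balanced" else "raw")
}

#' Write a contact matrix as a single-resolution cooler file
#'
#' Emits the standard cooler HDF5 layout (\code{chroms}, \code{bins},
#' \code{pixels}, \code{indexes} with upper-triangle pixels) so the file is
#' readable both by \code{\link{read_contact_matrix}} and by external
#' cooler tooling.
#'
#' @param cm a \code{contact_matrix} (tag \code{"raw"}; counts are written
#'   as stored).
#' @param path output \code{.cool} path.
#' @param weights optional per-bin balancing weight vector to store.
#' @param chrom_length chromosome length in bp; defaults to the region end.
#' @return \code{path}, invisibly.
#' @export
write_cooler <- function(cm, path, weights = NULL, chrom_length = NULL) {
  stopifnot(inherits(cm, "contact_matrix"))
  reg <- cm$region
  if (is.null(chrom_length)) chrom_length <- reg$end
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(format(cm$values, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     tmp, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  args <- c("create", shQuote(path), shQuote(reg$chrom),
            format(reg$start, scientific = FALSE),
            format(reg$end, scientific = FALSE),
            format(reg$resolution, scientific = FALSE),
            format(chrom_length, scientific = FALSE),
            "--matrix", shQuote(tmp))
  if (!is.null(weights)) {
    if (length(weights) != n_bins(reg))
      stop("weights length must equal n_bins")
    wtmp <- tempfile(fileext = ".txt")
    on.exit(unlink(wtmp), add = TRUE)
    writeLines(format(weights, digits = 17, trim = TRUE,
                      scientific = FALSE), wtmp)
    args <- c(args, "--weights", shQuote(wtmp))
  }
  run_cooler_helper(args)
  invisible(path)
}
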