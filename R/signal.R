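#' Unit-scaled signal
#'
#' A length-n vector scaled into [0, 1], as produced by
#' \code{\link{scale_unit}}. \code{branch} records whether the values came
#' from an unsigned track, or from the positive or negative part of a
#' signed track (negatives are negated before transformation).
#'
#' @param values numeric vector in [0, 1] (NA allowed).
#' @param transform_log whether log1p was applied before scaling.
#' @param branch one of \code{"unsigned"}, \code{"positive"},
#'   \code{"negative"}.
#' @param name label carried into layers.
#' @return An object of class \code{unit_signal}.
#' @export
unit_signal <- function(values, transform_log = FALSE,
                        branch = "unsigned", name = "signal") {
  values <- as.numeric(values)
  branch <- match.arg(branch, c("unsigned", "positive", "negative"))
  if (any(values < -1e-12 | values > 1 + 1e-12, na.rm = TRUE))
    stop("unit signal values must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  structure(list(values = values, transform_log = transform_log,
                 branch = branch, name = name),
            class = "unit_signal")
}

#' @export
print.unit_signal <- function(x, ...) {
  cat(sprintf("<unit_signal> '%s' (%s), n=%d%s; %d NA\n", x$name, x$branch,
              length(x$values), if (x$transform_log) ", log1p" else "",
              sum(is.na(x$values))))
  invisible(x)
}

# min-max to [0,1] over non-missing values; flat input maps to all zeros
# (a flat track carries no local enrichment -> fully transparent layer).
minmax01 <- function(v) {
  ok <- !is.na(v)
  if (!any(ok)) stop("all values missing; cannot scale")
  lo <- min(v[ok]); hi <- max(v[ok])
  if (hi == lo) {
    v[ok] <- 0
    return(v)
  }
  (v - lo) / (hi - lo)
}

#' Scale a track to the unit interval
#'
#' Applies, in order: the signed-track split (negatives negated into their
#' own branch), the optional \code{log1p} transform, optional clamping, and
#' min-max scaling of the region's non-missing values so that the local
#' minimum maps to 0 and the local maximum to 1. A constant track scales to
#' all zeros (no local enrichment). Missing bins stay missing.
#'
#' Signed tracks return a list with elements \code{positive} and
#' \code{negative}; each branch zeroes the other sign's bins and is scaled
#' independently, so weak compartments of either sign remain visible.
#'
#' @param track a \code{\link{binned_track}}.
#' @param use_log apply \code{log1p} before scaling.
#' @param clamp optional length-2 bounds applied before scaling; values
#'   outside are truncated. Interpreted as quantiles of the non-missing
#'   values when \code{clamp_quantile = TRUE}, otherwise as absolute bounds
#'   (on the post-log scale when \code{use_log}).
#' @param clamp_quantile treat \code{clamp} as quantile probabilities.
#' @return A \code{\link{unit_signal}}, or a list of two (positive and
#'   negative branches) for signed tracks.
#' @examples
#' r <- genomic_region("chr1", 0, 3e4, 1e4)
#' scale_unit(binned_track(c(0, 5, 10), r))$values  # 0, 0.5, 1
#' @export
scale_unit <- function(track, use_log = FALSE, clamp = NULL,
                       clamp_quantile = FALSE) {
  stopifnot(inherits(track, "binned_track"))
  one_branch <- function(v, branch) {
    if (use_log) v <- log1p(v)
    if (!is.null(clamp)) {
      stopifnot(length(clamp) == 2, clamp[1] <= clamp[2])
      bounds <- if (clamp_quantile)
        stats::quantile(v, probs = clamp, na.rm = TRUE, names = FALSE)
      else clamp
      v <- pmin(pmax(v, bounds[1]), bounds[2])
    }
    unit_signal(minmax01(v), transform_log = use_log, branch = branch,
                name = track$name)
  }
  v <- track$values
  if (!any(!is.na(v))) stop("all values missing in track '", track$name, "'")
  if (!track$signed)
    return(one_branch(v, "unsigned"))
  pos <- ifelse(is.na(v), NA_real_, pmax(v, 0))
  neg <- ifelse(is.na(v), NA_real_, pmax(-v, 0))
  list(positive = one_branch(pos, "positive"),
       negative = one_branch(neg, "negative"))
}

#' 2D signal matrix
#'
#' n x n matrix in [0, 1] derived from unit signals:
#' \code{m[i,j] = s[i] * s[j]} (standard, symmetric) or
#' \code{m[i,j] = s1[i] * s2[j]} (vs mode, generally asymmetric).
#'
#' @param values numeric matrix in [0, 1].
#' @param mode \code{"standard"} or \code{"vs"}.
#' @param name label.
#' @return An object of class \code{signal_matrix}.
#' @export
new_signal_matrix <- function(values, mode = "standard", name = "signal") {
  mode <- match.arg(mode, c("standard", "vs"))
  values <- as.matrix(values)
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("signal matrix entries must lie in [0, 1]")
  structure(list(values = values, mode = mode, name = name),
            class = "signal_matrix")
}

#' Outer-product signal matrix
#'
#' Lifts a unit signal to two dimensions: \code{m[i,j] = s[i] * s[j]}, so a
#' pixel is bright only when both its row and column bins carry signal.
#' An entry is missing if either factor is missing.
#'
#' @param s a \code{\link{unit_signal}}.
#' @return A symmetric \code{signal_matrix} (mode \code{"standard"}).
#' @export
signal_matrix <- function(s) {
  stopifnot(inherits(s, "unit_signal"))
  new_signal_matrix(outer(s$values, s$values), "standard", name = s$name)
}

#' Two-signal ("vs") signal matrix
#'
#' \code{m[i,j] = s1[i] * s2[j]}: rows are weighted by one track, columns
#' by another, highlighting interactions whose two anchors are occupied by
#' different factors. Reduces to \code{\link{signal_matrix}} when
#' \code{s1 == s2}.
#'
#' @param s1,s2 \code{\link{unit_signal}}s of equal length.
#' @return A \code{signal_matrix} with mode \code{"vs"}.
#' @export
signal_matrix_vs <- function(s1, s2) {
  stopifnot(inherits(s1, "unit_signal"), inherits(s2, "unit_signal"))
  if (length(s1$values) != length(s2$values))
    stop("signals have different lengths (", length(s1$values), " vs ",
         length(s2$values), ")")
  new_signal_matrix(outer(s1$values, s2$values), "vs",
                    name = paste0(s1$name, " vs ", s2$name))
}

#' Unit-scale a contact matrix
#'
#' Min-max scales the non-missing entries to [0, 1]; a constant matrix
#' scales to all zeros. The result carries
#' \code{normalization_tag = "unit-scaled"}.
#'
#' @param cm a \code{\link{contact_matrix}}.
#' @return A unit-scaled \code{contact_matrix}.
#' @export
scale_contacts <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  if (!any(!is.na(cm$values))) stop("all contact entries missing")
  contact_matrix(minmax01(cm$values), cm$region, "unit-scaled")
}

#' Distance-normalize a contact matrix
#'
#' Removes the distance-decay trend: for each diagonal offset d within the
#' region, the expected value is the mean of the non-missing observed
#' entries at that offset, and every entry becomes
#' \code{(observed + 1) / (expected + 1)}. Offsets whose entries are all
#' missing stay missing. The expected profile is computed within the
#' displayed region.
#'
#' @param cm a \code{\link{contact_matrix}}.
#' @return A \code{contact_matrix} tagged \code{"distnorm"}.
#' @export
distance_normalize <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  v <- cm$values
  n <- nrow(v)
  d <- abs(row(v) - col(v))
  expected <- vapply(0:(n - 1), function(k) {
    x <- v[d == k]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  out <- (v + 1) / (expected[d + 1] + 1)
  contact_matrix(out, cm$region, "distnorm")
}
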