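#' Classify bins by their dominant mark
#'
#' A bin is classed to mark M when M's value at that bin lies in M's own
#' top quantile and no other mark's value lies in its own top quantile
#' there; bins high for zero or several marks stay unassigned. This
#' operationalizes "bins with high levels" of a mark as an exclusive
#' top-quantile rule.
#'
#' @param tracks named list of \code{\link{binned_track}}s over the same
#'   region (names default to the track names).
#' @param quantile threshold level in (0, 1); default 0.9 (top 10%).
#' @return An object of class \code{bin_classification} with fields
#'   \code{region}, \code{class_of_bin} (character, NA = unassigned) and
#'   \code{threshold_rule}.
#' @export
classify_bins <- function(tracks, quantile = 0.9) {
  stopifnot(is.list(tracks), length(tracks) >= 1,
            all(vapply(tracks, inherits, TRUE, "binned_track")),
            quantile > 0, quantile < 1)
  region <- tracks[[1]]$region
  for (tr in tracks)
    if (!same_region(tr$region, region))
      stop("tracks do not share a region")
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    names(tracks) <- vapply(tracks, `[[`, "", "name")
  high <- vapply(tracks, function(tr) {
    thr <- stats::quantile(tr$values, probs = quantile, na.rm = TRUE,
                           names = FALSE)
    !is.na(tr$values) & tr$values >= thr
  }, logical(n_bins(region)))
  high <- matrix(high, nrow = n_bins(region))
  nhigh <- rowSums(high)
  cls <- rep(NA_character_, n_bins(region))
  one <- nhigh == 1
  cls[one] <- names(tracks)[apply(high[one, , drop = FALSE], 1, which)]
  structure(list(region = region, class_of_bin = cls,
                 threshold_rule = sprintf(
                   "exclusive top-quantile (q = %g) per mark", quantile)),
            class = "bin_classification")
}

#' @export
print.bin_classification <- function(x, ...) {
  tab <- table(x$class_of_bin, useNA = "ifany")
  cat(sprintf("<bin_classification> %s; %s\n", format(x$region),
              x$threshold_rule))
  print(tab)
  invisible(x)
}

#' Quantify per-mark signal within same-class interactions
#'
#' For each class C, collects every layer's alpha over the pixels
#' \code{(i, j)} with \code{i <= j} whose two bins are both classed C
#' (each unordered pair counted once, diagonal included), then runs
#' two-sided Wilcoxon rank-sum tests between the matched layer (label
#' equal to C) and each non-matched layer within that class. Strong
#' separation — matched alphas high, non-matched low — is the signature
#' of marks forming distinct compartment interactions.
#'
#' @param classification a \code{\link{bin_classification}}.
#' @param layers list of \code{\link{color_layer}}s whose labels include
#'   the class names.
#' @param exact use the exact rank-sum distribution (small samples,
#'   no ties); default uses the normal approximation with tie correction.
#' @return An object of class \code{overlap_quant}: \code{summary}
#'   (class, layer, n, median alpha), \code{tests} (class, matched vs
#'   other layer, group sizes, W, p), and \code{samples} (the raw alpha
#'   multisets, a nested list).
#' @export
quantify_overlap <- function(classification, layers, exact = FALSE) {
  stopifnot(inherits(classification, "bin_classification"))
  if (inherits(layers, "color_layer")) layers <- list(layers)
  stopifnot(all(vapply(layers, inherits, TRUE, "color_layer")))
  labels <- vapply(layers, `[[`, "", "label")
  names(layers) <- labels
  nb <- length(classification$class_of_bin)
  if (any(vapply(layers, function(l) nrow(l$alpha), 0L) != nb))
    stop("layer dimension does not match classification bins")
  classes <- unique(stats::na.omit(classification$class_of_bin))
  summary_rows <- list(); test_rows <- list(); samples <- list()
  for (cl in classes) {
    bins <- which(classification$class_of_bin == cl)
    pairs <- which(upper.tri(matrix(0, nb, nb), diag = TRUE) &
                   outer(seq_len(nb) %in% bins, seq_len(nb) %in% bins, `&`))
    if (length(pairs) == 0) {
      warning("class '", cl, "' has zero pixels; skipped")
      next
    }
    samples[[cl]] <- lapply(layers, function(l) as.numeric(l$alpha[pairs]))
    for (lb in labels)
      summary_rows[[length(summary_rows) + 1]] <- data.frame(
        class = cl, layer = lb, n = length(pairs),
        median = stats::median(samples[[cl]][[lb]]),
        stringsAsFactors = FALSE)
    if (cl %in% labels) {
      matched <- samples[[cl]][[cl]]
      for (lb in setdiff(labels, cl)) {
        other <- samples[[cl]][[lb]]
        wt <- suppressWarnings(
          stats::wilcox.test(matched, other, exact = exact,
                             correct = !exact))
        test_rows[[length(test_rows) + 1]] <- data.frame(
          class = cl, matched_layer = cl, other_layer = lb,
          n_matched = length(matched), n_other = length(other),
          statistic = unname(wt$statistic), p = wt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 tests = if (length(test_rows)) do.call(rbind, test_rows)
                         else NULL,
                 samples = samples,
                 threshold_rule = classification$threshold_rule),
            class = "overlap_quant")
}

#' @export
print.overlap_quant <- function(x, ...) {
  cat("<overlap_quant> per-class layer alpha medians:\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("rank-sum tests (matched vs other layer within class):\n")
    print(x$tests, row.names = FALSE)
  }
  invisible(x)
}

#' Write overlap quantification as a TSV table
#'
#' One row per (class, layer): n, median alpha, and — for non-matched
#' layers — the rank-sum statistic and p-value against the matched layer.
#'
#' @param x an \code{\link{quantify_overlap}} result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_overlap_tsv <- function(x, path) {
  stopifnot(inherits(x, "overlap_quant"))
  df <- x$summary
  df$statistic <- NA_real_; df$p <- NA_real_
  if (!is.null(x$tests)) {
    for (k in seq_len(nrow(x$tests))) {
      i <- which(df$class == x$tests$class[k] &
                 df$layer == x$tests$other_layer[k])
      df$statistic[i] <- x$tests$statistic[k]
      df$p[i] <- x$tests$p[k]
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
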