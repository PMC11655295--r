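#' Parse a color to an RGB triple
#'
#' Accepts hex strings (\code{"#RRGGBB"}), R color names, or a numeric
#' length-3 vector already in 0-255.
#'
#' @param color color specification.
#' @return Integer vector \code{c(r, g, b)} in 0-255.
#' @export
parse_color <- function(color) {
  if (is.numeric(color)) {
    stopifnot(length(color) == 3, all(color >= 0 & color <= 255))
    return(as.integer(round(color)))
  }
  as.integer(grDevices::col2rgb(color)[, 1])
}

# round half away from zero, once, at 8-bit conversion
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Color layer: one track rendered as a constant-hue alpha image
#'
#' A single RGB color plus an n x n integer alpha matrix in 0-255. The
#' alpha encodes joint 1D-signal and contact intensity; missing pixels have
#' alpha 0.
#'
#' @param rgb integer \code{c(r, g, b)} in 0-255.
#' @param alpha n x n integer matrix in 0-255.
#' @param label layer name.
#' @return An object of class \code{color_layer}.
#' @export
color_layer <- function(rgb, alpha, label = "layer") {
  rgb <- parse_color(rgb)
  alpha <- as.matrix(alpha)
  if (any(is.na(alpha))) stop("alpha must not contain NA; use 0")
  if (any(alpha < 0 | alpha > 255)) stop("alpha entries must be in 0-255")
  storage.mode(alpha) <- "integer"
  structure(list(rgb = rgb, alpha = alpha, label = label),
            class = "color_layer")
}

#' @export
print.color_layer <- function(x, ...) {
  cat(sprintf("<color_layer> '%s' rgb(%d,%d,%d), %d x %d, max alpha %d\n",
              x$label, x$rgb[1], x$rgb[2], x$rgb[3],
              nrow(x$alpha), ncol(x$alpha), max(x$alpha)))
  invisible(x)
}

#' Compose a signal matrix and contact map into a color layer
#'
#' The per-pixel opacity is the 8-bit conversion of the product of signal
#' matrix, unit-scaled contact map and overlay strength:
#' \code{alpha[i,j] = round(m[i,j] * c[i,j] * overlay_strength * 255)},
#' rounding half away from zero, applied once here. Pixels missing in
#' either factor are fully transparent.
#'
#' @param m a \code{\link{signal_matrix}}.
#' @param c_scaled a unit-scaled \code{\link{contact_matrix}} (see
#'   \code{\link{scale_contacts}}).
#' @param rgb layer color (hex, name, or 0-255 triple).
#' @param overlay_strength degree of overlay in [0, 1]; scales all alphas.
#' @return A \code{\link{color_layer}}.
#' @export
compose_layer <- function(m, c_scaled, rgb, overlay_strength = 1) {
  stopifnot(inherits(m, "signal_matrix"),
            inherits(c_scaled, "contact_matrix"))
  if (c_scaled$normalization_tag != "unit-scaled")
    stop("contact matrix must be unit-scaled; call scale_contacts() first")
  if (!identical(dim(m$values), dim(c_scaled$values)))
    stop("signal matrix and contact matrix dimensions differ")
  stopifnot(overlay_strength >= 0, overlay_strength <= 1)
  a <- round_half_away(m$values * c_scaled$values * overlay_strength * 255)
  a[is.na(a)] <- 0
  color_layer(rgb, a, label = m$name)
}

#' Blended multi-track image
#'
#' Result of \code{\link{blend_layers}}: per-pixel mixed color channels and
#' a total alpha clipped to the 8-bit maximum. Zero-alpha pixels carry the
#' background color (white when flattened to PNG; transparent in SVG).
#'
#' @param rgb_channels n x n x 3 integer array in 0-255.
#' @param alpha n x n integer matrix in 0-255.
#' @return An object of class \code{blended_image}.
#' @export
blended_image <- function(rgb_channels, alpha) {
  stopifnot(length(dim(rgb_channels)) == 3, dim(rgb_channels)[3] == 3)
  storage.mode(rgb_channels) <- "integer"
  storage.mode(alpha) <- "integer"
  structure(list(rgb_channels = rgb_channels, alpha = alpha),
            class = "blended_image")
}

#' Blend color layers by alpha-weighted linear interpolation
#'
#' Per pixel, with layer alphas \eqn{\alpha_b}: the total alpha is
#' \eqn{\sum_b \alpha_b}, each layer's blend ratio is
#' \eqn{\alpha_b / \sum_b \alpha_b}, the mixed color channels are the
#' ratio-weighted sums of the layer colors, and the final alpha is the
#' total clipped to 255. Pixels where every layer is transparent take the
#' white background with alpha 0. Mixing happens on the 0-255 integers in
#' linear RGB with a single rounding at output.
#'
#' @param layers list of \code{\link{color_layer}}s of equal dimension.
#' @return A \code{\link{blended_image}}.
#' @export
blend_layers <- function(layers) {
  if (inherits(layers, "color_layer")) layers <- list(layers)
  if (length(layers) == 0) stop("need at least one layer")
  stopifnot(all(vapply(layers, inherits, TRUE, "color_layer")))
  dims <- lapply(layers, function(l) dim(l$alpha))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("layers have differing dimensions")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  total <- Reduce(`+`, lapply(layers, function(l) l$alpha))
  # blend ratio alpha_b / total folded into a single integer numerator
  # sum and one exact division: order-invariant and reproducible at
  # exact-half rounding boundaries
  mixed <- array(0, dim = c(nr, nc, 3))
  safe_total <- ifelse(total > 0, total, 1)
  for (ch in 1:3) {
    num <- Reduce(`+`, lapply(layers, function(l) l$rgb[ch] * l$alpha))
    mixed[, , ch] <- round_half_away(num / safe_total)
  }
  for (ch in 1:3) {
    m <- mixed[, , ch]
    m[total == 0] <- 255  # background
    mixed[, , ch] <- m
  }
  blended_image(mixed, pmin(total, 255L))
}

#' Two-color compartment layers from a signed eigenvector track
#'
#' Splits a signed track (positive = A compartment, negative = B) into its
#' branches, scales each independently, lifts each to an outer-product
#' signal matrix and composes it with the contact map. A pixel whose two
#' bins disagree in sign is transparent in both layers: it belongs to
#' neither same-compartment set.
#'
#' @param eig a signed \code{\link{binned_track}}.
#' @param c_scaled a unit-scaled \code{\link{contact_matrix}}.
#' @param rgb_A,rgb_B colors for the positive (A) and negative (B) layers.
#' @param use_log apply log1p within each branch before scaling.
#' @param overlay_strength degree of overlay in [0, 1].
#' @return List with elements \code{A} and \code{B}, each a
#'   \code{\link{color_layer}}.
#' @export
eigen_layers <- function(eig, c_scaled, rgb_A = "#E41A1C",
                         rgb_B = "#377EB8", use_log = FALSE,
                         overlay_strength = 1) {
  stopifnot(inherits(eig, "binned_track"))
  if (!eig$signed)
    stop("eigenvector mode needs a signed track (signed = TRUE)")
  s <- scale_unit(eig, use_log = use_log)
  a <- compose_layer(signal_matrix(s$positive), c_scaled, rgb_A,
                     overlay_strength)
  b <- compose_layer(signal_matrix(s$negative), c_scaled, rgb_B,
                     overlay_strength)
  a$label <- paste0(eig$name, ":A")
  b$label <- paste0(eig$name, ":B")
  list(A = a, B = b)
}

#' Assign bins to chromHMM states by largest overlap
#'
#' Each bin goes to the state covering most of its bases; ties break to
#' the state seen first in the file. Bins with no overlapping interval are
#' unassigned (\code{NA}).
#'
#' @param seg a \code{\link{chromhmm_segmentation}}.
#' @param region a \code{\link{genomic_region}}.
#' @return Character vector of per-bin state labels (NA = unassigned).
#' @export
assign_chromhmm_bins <- function(seg, region) {
  stopifnot(inherits(seg, "chromhmm_segmentation"))
  nb <- n_bins(region)
  res <- region$resolution
  labels <- seg$states$state
  ov <- matrix(0, nrow = nb, ncol = length(labels),
               dimnames = list(NULL, labels))
  iv <- seg$intervals[seg$intervals$chrom == region$chrom, ]
  for (k in seq_len(nrow(iv))) {
    s <- max(iv$start[k], region$start)
    e <- min(iv$end[k], region$end)
    if (e <= s) next
    b0 <- floor((s - region$start) / res)
    b1 <- ceiling((e - region$start) / res) - 1
    for (b in b0:b1) {
      lo <- region$start + b * res
      w <- min(e, lo + res) - max(s, lo)
      ov[b + 1, iv$state[k]] <- ov[b + 1, iv$state[k]] + w
    }
  }
  out <- rep(NA_character_, nb)
  hit <- rowSums(ov) > 0
  # which.max keeps the first maximum -> first-seen state wins ties
  out[hit] <- labels[apply(ov[hit, , drop = FALSE], 1, which.max)]
  out
}

#' Per-state color layers from a chromHMM segmentation
#'
#' Builds one binary membership track per selected state (bin assigned by
#' largest overlap), lifts each to an outer-product signal matrix, and
#' composes it with the contact map using the state's own RGB color from
#' the file. The returned layers feed \code{\link{blend_layers}}.
#'
#' @param seg a \code{\link{chromhmm_segmentation}}.
#' @param region a \code{\link{genomic_region}}.
#' @param c_scaled a unit-scaled \code{\link{contact_matrix}}.
#' @param states optional subset of state labels to render (default all,
#'   in first-seen order).
#' @param overlay_strength degree of overlay in [0, 1].
#' @return List of \code{\link{color_layer}}s, one per selected state.
#' @export
chromhmm_layers <- function(seg, region, c_scaled, states = NULL,
                            overlay_strength = 1) {
  stopifnot(inherits(seg, "chromhmm_segmentation"))
  if (is.null(states)) states <- seg$states$state
  missing_states <- setdiff(states, seg$states$state)
  if (length(missing_states) > 0)
    stop("requested state(s) absent from segmentation: ",
         paste(missing_states, collapse = ", "))
  assignment <- assign_chromhmm_bins(seg, region)
  lapply(states, function(st) {
    member <- as.numeric(!is.na(assignment) & assignment == st)
    # binary membership is already a unit signal; no min-max rescaling
    s <- unit_signal(member, name = st)
    col <- seg$states[seg$states$state == st, c("r", "g", "b")]
    compose_layer(signal_matrix(s), c_scaled, as.numeric(col),
                  overlay_strength)
  })
}
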