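#' Rendering specification
#'
#' Everything needed to produce an image: the region, the contact-matrix
#' source and its normalization chain (balance, then distance
#' normalization, then unit scaling — each optional except the final unit
#' scaling, which always runs), the track list, the coloring mode, and the
#' output target.
#'
#' @param region a \code{\link{genomic_region}}.
#' @param matrix_source path to a cooler or dense-text contact matrix.
#' @param tracks list of track specs, each a list with \code{path},
#'   \code{color}, and optional \code{log}, \code{signed} flags.
#' @param mode one of \code{"individual"}, \code{"blended"}, \code{"vs"},
#'   \code{"eigen"}, \code{"chromhmm"}. \code{"vs"} needs exactly two
#'   tracks; \code{"eigen"} exactly one signed track; \code{"individual"}
#'   exactly one track.
#' @param balance use stored balancing weights (cooler sources).
#' @param distnorm apply \code{\link{distance_normalize}} before unit
#'   scaling.
#' @param overlay_strength degree of overlay in [0, 1].
#' @param underlay draw the un-colored contact map underneath as a
#'   grayscale layer of strength \code{1 - overlay_strength}.
#' @param segmentation path to a chromHMM BED9 (chromhmm mode).
#' @param states optional state subset (chromhmm mode).
#' @param color_negative color of the negative (B-compartment) layer in
#'   eigen mode; the track's own color is the positive layer.
#' @param out output file path.
#' @param format \code{"png"} or \code{"svg"}; default from \code{out}
#'   extension.
#' @return An object of class \code{render_spec}.
#' @export
render_spec <- function(region, matrix_source, tracks = list(),
                        mode = "blended", balance = FALSE,
                        distnorm = FALSE, overlay_strength = 1,
                        underlay = FALSE, segmentation = NULL,
                        states = NULL, color_negative = "#377EB8",
                        out = NULL, format = NULL) {
  mode <- match.arg(mode,
                    c("individual", "blended", "vs", "eigen", "chromhmm"))
  tracks <- lapply(tracks, function(tr) {
    stopifnot(!is.null(tr$path))
    if (is.null(tr$color)) tr$color <- "#E41A1C"
    if (is.null(tr$log)) tr$log <- FALSE
    if (is.null(tr$signed)) tr$signed <- FALSE
    tr
  })
  if (mode == "vs" && length(tracks) != 2)
    stop("vs mode requires exactly two tracks")
  if (mode == "individual" && length(tracks) != 1)
    stop("individual mode requires exactly one track")
  if (mode == "eigen") {
    if (length(tracks) != 1 || !tracks[[1]]$signed)
      stop("eigen mode requires exactly one signed track")
  }
  if (mode == "chromhmm" && is.null(segmentation))
    stop("chromhmm mode requires a segmentation file")
  if (is.null(format) && !is.null(out))
    format <- tolower(tools::file_ext(out))
  if (!is.null(format)) format <- match.arg(format, c("png", "svg"))
  structure(list(region = region, matrix_source = matrix_source,
                 tracks = tracks, mode = mode, balance = balance,
                 distnorm = distnorm,
                 overlay_strength = overlay_strength,
                 underlay = underlay, segmentation = segmentation,
                 states = states, color_negative = color_negative,
                 out = out, format = format),
            class = "render_spec")
}

build_layers <- function(spec) {
  cm <- read_contact_matrix(spec$matrix_source, spec$region,
                            balance = spec$balance)
  if (spec$distnorm) cm <- distance_normalize(cm)
  cs <- scale_contacts(cm)
  region <- cm$region
  read_spec_track <- function(tr)
    read_track(tr$path, region, signed = tr$signed)
  layers <- switch(spec$mode,
    individual = ,
    blended = lapply(spec$tracks, function(tr) {
      s <- scale_unit(read_spec_track(tr), use_log = tr$log)
      compose_layer(signal_matrix(s), cs, tr$color,
                    spec$overlay_strength)
    }),
    vs = {
      s1 <- scale_unit(read_spec_track(spec$tracks[[1]]),
                       use_log = spec$tracks[[1]]$log)
      s2 <- scale_unit(read_spec_track(spec$tracks[[2]]),
                       use_log = spec$tracks[[2]]$log)
      list(compose_layer(signal_matrix_vs(s1, s2), cs,
                         spec$tracks[[1]]$color, spec$overlay_strength))
    },
    eigen = {
      tr <- spec$tracks[[1]]
      unname(eigen_layers(read_spec_track(tr), cs, rgb_A = tr$color,
                          rgb_B = spec$color_negative,
                          use_log = tr$log,
                          overlay_strength = spec$overlay_strength))
    },
    chromhmm = {
      seg <- read_chromhmm(spec$segmentation, region)
      chromhmm_layers(seg, region, cs, states = spec$states,
                      overlay_strength = spec$overlay_strength)
    })
  if (spec$underlay) {
    v <- cs$values
    v[is.na(v)] <- 0
    a <- round_half_away(v * (1 - spec$overlay_strength) * 255)
    layers <- c(list(color_layer(c(0, 0, 0), a, "hic")), layers)
  }
  list(layers = layers, contacts = cs, region = region)
}

#' Flatten a blended image onto a background
#'
#' Standard source-over flattening of the premixed color against an opaque
#' background: \code{out = bg * (1 - a/255) + rgb * a/255}, rounded half
#' away from zero.
#'
#' @param img a \code{\link{blended_image}}.
#' @param background length-3 RGB in 0-255 (default white).
#' @return n x n x 3 integer array.
#' @export
flatten_image <- function(img, background = c(255, 255, 255)) {
  stopifnot(inherits(img, "blended_image"))
  a <- img$alpha / 255
  out <- array(0L, dim = dim(img$rgb_channels))
  for (ch in 1:3)
    out[, , ch] <- as.integer(round_half_away(
      background[ch] * (1 - a) + img$rgb_channels[, , ch] * a))
  out
}

#' Render a specification to an image file
#'
#' Runs the full pipeline (read, normalize, scale, colorize, blend) and
#' writes either a PNG — the flattened pixel matrix, byte-stable across
#' runs, row 1 at top, both axes in genomic coordinates by construction —
#' or an SVG with one group per layer (each an embedded lossless raster),
#' axis coordinate labels, and a transparent background.
#'
#' @param spec a \code{\link{render_spec}} with \code{out} set.
#' @return The \code{\link{blended_image}}, invisibly.
#' @export
render <- function(spec) {
  stopifnot(inherits(spec, "render_spec"))
  if (is.null(spec$out)) stop("render_spec has no output path")
  built <- build_layers(spec)
  img <- blend_layers(built$layers)
  fmt <- spec$format
  if (is.null(fmt)) fmt <- tolower(tools::file_ext(spec$out))
  if (fmt == "png") {
    flat <- flatten_image(img)
    png::writePNG(flat / 255, spec$out)
  } else if (fmt == "svg") {
    write_svg(built$layers, built$region, spec$out)
  } else stop("unknown output format '", fmt, "'")
  invisible(img)
}

layer_png_base64 <- function(layer) {
  n <- nrow(layer$alpha)
  arr <- array(0, dim = c(n, ncol(layer$alpha), 4))
  for (ch in 1:3) arr[, , ch] <- layer$rgb[ch] / 255
  arr[, , 4] <- layer$alpha / 255
  jsonlite::base64_enc(png::writePNG(arr))
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_svg <- function(layers, region, path, cell = 4, margin = 60) {
  n <- nrow(layers[[1]]$alpha)
  side <- n * cell
  w <- side + 2 * margin
  lines <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
           'xmlns:xlink="http://www.w3.org/1999/xlink" ',
           'width="%d" height="%d" viewBox="0 0 %d %d">'), w, w, w, w))
  ticks <- pretty(c(region$start, region$end), n = 5)
  ticks <- ticks[ticks >= region$start & ticks <= region$end]
  px <- function(coord)
    margin + (coord - region$start) / (region$end - region$start) * side
  for (t in ticks) {
    lines <- c(lines,
      sprintf('<text x="%.1f" y="%.1f" font-size="10" text-anchor="middle">%s</text>',
              px(t), margin - 8, format(t, scientific = FALSE,
                                        big.mark = ",")),
      sprintf('<text x="%.1f" y="%.1f" font-size="10" text-anchor="end">%s</text>',
              margin - 8, px(t) + 3, format(t, scientific = FALSE,
                                            big.mark = ",")))
  }
  lines <- c(lines, sprintf(
    '<text x="%.1f" y="%.1f" font-size="11" text-anchor="middle">%s</text>',
    margin + side / 2, w - margin / 3,
    svg_escape(format.genomic_region(region))))
  for (l in layers) {
    lines <- c(lines,
      sprintf('<g id="%s">', svg_escape(l$label)),
      sprintf(paste0('<image x="%d" y="%d" width="%d" height="%d" ',
                     'preserveAspectRatio="none" ',
                     'style="image-rendering:pixelated" ',
                     'xlink:href="data:image/png;base64,%s"/>'),
              margin, margin, side, side, layer_png_base64(l)),
      '</g>')
  }
  lines <- c(lines,
    sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="none" stroke="black" stroke-width="1"/>',
            margin, margin, side, side),
    '</svg>')
  writeLines(lines, path)
  invisible(path)
}
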