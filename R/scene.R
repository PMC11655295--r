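#' Specification for a synthetic chromatin scene
#'
#' Describes a compartmentalized contact map with matching 1D tracks: a
#' per-bin state vector, a state-affinity matrix of contact means, a
#' power-law distance decay, overdispersed count noise, optional punctate
#' loops, and per-state mark emission. The defaults emulate a region with
#' three mutually exclusive chromatin flavors — active (H3K27ac),
#' heterochromatin (H3K9me3) and Polycomb (H3K27me3) — each occupying two
#' 10-bin domains (10% of bins per mark) in a neutral background, so that
#' a top-decile threshold delineates each mark's domains.
#'
#' @param n_bins number of bins (default 200).
#' @param resolution bin width in bp (default 10000).
#' @param chrom chromosome name of the synthetic scene.
#' @param seed RNG seed; the same seed reproduces the scene exactly.
#' @param states per-bin state labels; default layout places two domains
#'   per mark state in a neutral (\code{"N"}) background.
#' @param affinity named square matrix of state-pair contact multipliers.
#' @param base_mean contact mean scale at distance 0 for affinity 1.
#' @param decay_gamma power-law distance-decay exponent:
#'   mean multiplier \code{(|i-j|+1)^(-decay_gamma)}.
#' @param dispersion negative-binomial overdispersion (gamma-mixed
#'   Poisson); 0 gives the noise-free mean model.
#' @param loops data.frame with columns \code{i}, \code{j},
#'   \code{intensity}, \code{width}: Gaussian contact boosts.
#' @param mark_states named character vector mapping mark track names to
#'   the state they decorate.
#' @param emission_high,emission_low mark emission means on own-state and
#'   other bins.
#' @param emission_sd lognormal noise sd (log scale) on mark emissions.
#' @param eigen_sd Gaussian noise sd on the compartment-score track.
#' @param state_colors named list of RGB triples per state for the
#'   chromHMM-style segmentation.
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(n_bins = 200,
                       resolution = 10000,
                       chrom = "chrS",
                       seed = 42,
                       states = NULL,
                       affinity = NULL,
                       base_mean = 100,
                       decay_gamma = 1,
                       dispersion = 0.05,
                       loops = NULL,
                       mark_states = c(H3K27ac = "A", H3K9me3 = "B",
                                       H3K27me3 = "P"),
                       emission_high = 10,
                       emission_low = 0.5,
                       emission_sd = 0.25,
                       eigen_sd = 0.05,
                       state_colors = list(
                         A = c(0, 128, 0), B = c(128, 0, 128),
                         P = c(255, 165, 0), N = c(200, 200, 200))) {
  if (is.null(states)) {
    states <- rep("N", n_bins)
    place <- function(v, at) {
      for (a in at) states[a:(a + 9)] <<- v
      invisible(NULL)
    }
    # two 10-bin domains per mark state, spread over the region
    stopifnot(n_bins >= 200)
    place("A", c(21, 111))
    place("B", c(51, 141))
    place("P", c(81, 171))
  }
  stopifnot(length(states) == n_bins)
  labs <- unique(states)
  if (is.null(affinity)) {
    all_labs <- union(labs, c("A", "B", "P", "N"))
    affinity <- matrix(0.25, length(all_labs), length(all_labs),
                       dimnames = list(all_labs, all_labs))
    diag(affinity) <- 3
    affinity["N", "N"] <- 1
    # A and B segregate strongly; neutral chromatin leans active;
    # Polycomb sits in between (its own compartment, weakly mixing)
    affinity["A", "B"] <- affinity["B", "A"] <- 0.1
    affinity["A", "N"] <- affinity["N", "A"] <- 0.9
    affinity["B", "N"] <- affinity["N", "B"] <- 0.3
    affinity["P", "N"] <- affinity["N", "P"] <- 0.6
  }
  stopifnot(all(labs %in% rownames(affinity)), all(affinity > 0))
  if (is.null(loops)) loops <- data.frame(i = integer(), j = integer(),
                                          intensity = numeric(),
                                          width = numeric())
  structure(list(n_bins = n_bins, resolution = resolution, chrom = chrom,
                 seed = seed, states = states, affinity = affinity,
                 base_mean = base_mean, decay_gamma = decay_gamma,
                 dispersion = dispersion, loops = loops,
                 mark_states = mark_states,
                 emission_high = emission_high,
                 emission_low = emission_low,
                 emission_sd = emission_sd, eigen_sd = eigen_sd,
                 state_colors = state_colors),
            class = "scene_spec")
}

scene_mean_matrix <- function(spec) {
  n <- spec$n_bins
  aff <- spec$affinity[spec$states, spec$states]
  d <- abs(row(aff) - col(aff))
  mu <- spec$base_mean * (d + 1)^(-spec$decay_gamma) * aff
  dimnames(mu) <- NULL
  if (nrow(spec$loops) > 0) {
    idx <- cbind(rep(seq_len(n), n), rep(seq_len(n), each = n))
    for (k in seq_len(nrow(spec$loops))) {
      g <- spec$loops$intensity[k] * exp(
        -((idx[, 1] - spec$loops$i[k])^2 +
          (idx[, 2] - spec$loops$j[k])^2) /
          (2 * spec$loops$width[k]^2))
      mu <- mu + matrix(g, n, n)
      g2 <- spec$loops$intensity[k] * exp(
        -((idx[, 1] - spec$loops$j[k])^2 +
          (idx[, 2] - spec$loops$i[k])^2) /
          (2 * spec$loops$width[k]^2))
      mu <- mu + matrix(g2, n, n)
    }
  }
  mu
}

#' Generate a synthetic scene
#'
#' Draws a symmetric contact matrix around the scene's mean model
#' (power-law decay times state affinity plus loop boosts; negative
#' binomial counts when \code{dispersion > 0}, the exact mean otherwise),
#' one mark track per entry of \code{mark_states} (high on its own state's
#' bins), a signed compartment-score track (positive on A bins, negative
#' on B bins, near zero elsewhere), and a chromHMM-style segmentation.
#' With \code{dir} set, all of it is also written to disk in standard
#' formats readable by the package's own readers.
#'
#' @param spec a \code{\link{scene_spec}}.
#' @param dir optional directory: writes \code{contacts.tsv} (dense text),
#'   \code{contacts.cool}, per-mark \code{<mark>.bedgraph} and
#'   \code{<mark>.bw}, \code{eigen.bedgraph}, \code{segmentation.bed}
#'   (BED9) and per-mark peak BED files.
#' @return A list with \code{spec}, \code{region}, \code{contacts}
#'   (raw \code{contact_matrix}), \code{mean_matrix}, \code{tracks}
#'   (named list of \code{binned_track}), \code{eigen} (signed track),
#'   \code{states}, \code{segmentation}, and \code{files} (named paths
#'   when \code{dir} was given).
#' @export
make_scene <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- spec$n_bins
  region <- genomic_region(spec$chrom, 0, n * spec$resolution,
                           spec$resolution)
  mu <- scene_mean_matrix(spec)
  if (spec$dispersion > 0) {
    up <- upper.tri(mu, diag = TRUE)
    vals <- matrix(0, n, n)
    vals[up] <- stats::rnbinom(sum(up), mu = mu[up],
                               size = 1 / spec$dispersion)
    vals <- vals + t(vals) - diag(diag(vals))
  } else {
    vals <- mu
  }
  contacts <- contact_matrix(vals, region, "raw")

  tracks <- lapply(names(spec$mark_states), function(mark) {
    own <- spec$states == spec$mark_states[[mark]]
    base <- ifelse(own, spec$emission_high, spec$emission_low)
    v <- base * exp(stats::rnorm(n, 0, spec$emission_sd))
    binned_track(v, region, name = mark)
  })
  names(tracks) <- names(spec$mark_states)

  escore <- ifelse(spec$states == "A", 1,
                   ifelse(spec$states == "B", -1, 0)) +
    stats::rnorm(n, 0, spec$eigen_sd)
  eigen_track <- binned_track(escore, region, name = "eigen",
                              signed = TRUE)

  seg <- chromhmm_segmentation(run_length_intervals(spec, region))

  out <- list(spec = spec, region = region, contacts = contacts,
              mean_matrix = mu, tracks = tracks, eigen = eigen_track,
              states = spec$states, segmentation = seg, files = NULL)
  if (!is.null(dir)) out$files <- write_scene_files(out, dir)
  out
}

run_length_intervals <- function(spec, region) {
  r <- rle(spec$states)
  ends <- cumsum(r$lengths) * region$resolution
  starts <- c(0, ends[-length(ends)])
  cols <- t(vapply(r$values,
                   function(s) as.numeric(spec$state_colors[[s]]),
                   numeric(3)))
  data.frame(chrom = region$chrom, start = starts, end = ends,
             state = r$values, r = cols[, 1], g = cols[, 2], b = cols[, 3],
             stringsAsFactors = FALSE)
}

write_bedgraph <- function(track, path) {
  region <- track$region
  starts <- bin_starts(region)
  keep <- !is.na(track$values)
  df <- data.frame(chrom = region$chrom,
                   start = format(starts[keep], scientific = FALSE),
                   end = format(starts[keep] + region$resolution,
                                scientific = FALSE),
                   value = format(track$values[keep], digits = 17,
                                  trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_bigwig <- function(track, path) {
  region <- track$region
  starts <- bin_starts(region)
  keep <- !is.na(track$values)
  gr <- GenomicRanges::GRanges(
    region$chrom,
    IRanges::IRanges(start = starts[keep] + 1,
                     width = region$resolution),
    score = track$values[keep])
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(region$end, region$chrom)
  rtracklayer::export.bw(gr, path)
  invisible(path)
}

write_scene_files <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region <- scene$region
  files <- list()
  files$dense <- file.path(dir, "contacts.tsv")
  write_dense_matrix(scene$contacts, files$dense)
  files$cool <- file.path(dir, "contacts.cool")
  write_cooler(scene$contacts, files$cool)
  for (mark in names(scene$tracks)) {
    bg <- file.path(dir, paste0(mark, ".bedgraph"))
    bw <- file.path(dir, paste0(mark, ".bw"))
    write_bedgraph(scene$tracks[[mark]], bg)
    write_bigwig(scene$tracks[[mark]], bw)
    files[[paste0(mark, "_bedgraph")]] <- bg
    files[[paste0(mark, "_bw")]] <- bw
    peaks <- file.path(dir, paste0(mark, "_peaks.bed"))
    own <- scene$states == scene$spec$mark_states[[mark]]
    r <- rle(own)
    ends <- cumsum(r$lengths) * region$resolution
    starts <- c(0, ends[-length(ends)])
    df <- data.frame(chrom = region$chrom,
                     start = format(starts[r$values],
                                    scientific = FALSE),
                     end = format(ends[r$values], scientific = FALSE))
    utils::write.table(df, peaks, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    files[[paste0(mark, "_peaks")]] <- peaks
  }
  files$eigen <- file.path(dir, "eigen.bedgraph")
  write_bedgraph(scene$eigen, files$eigen)
  files$segmentation <- file.path(dir, "segmentation.bed")
  seg <- scene$segmentation$intervals
  df <- data.frame(chrom = seg$chrom,
                   start = format(seg$start, scientific = FALSE),
                   end = format(seg$end, scientific = FALSE),
                   state = seg$state, score = 0, strand = ".",
                   thickStart = format(seg$start, scientific = FALSE),
                   thickEnd = format(seg$end, scientific = FALSE),
                   rgb = paste(seg$r, seg$g, seg$b, sep = ","))
  utils::write.table(df, files$segmentation, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files
}
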