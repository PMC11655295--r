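# Shared fixture builders. Everything is generated in code at test time.

tiny_region <- function(n = 4, res = 100, chrom = "chrT") {
  genomic_region(chrom, 0, n * res, res)
}

# per-base accumulation oracle for interval -> bin aggregation:
# value of bin k = mean over covered bases of the interval values
per_base_bin_oracle <- function(starts, ends, values, region,
                                empty = NA_real_) {
  nb <- n_bins(region)
  res <- region$resolution
  base_val <- rep(NA_real_, region$end - region$start)
  for (k in seq_along(starts)) {
    s <- max(starts[k], region$start); e <- min(ends[k], region$end)
    if (e > s) base_val[(s - region$start + 1):(e - region$start)] <- values[k]
  }
  vapply(seq_len(nb), function(b) {
    x <- base_val[((b - 1) * res + 1):(b * res)]
    if (all(is.na(x))) empty else mean(x, na.rm = TRUE)
  }, numeric(1))
}

write_bedgraph_file <- function(df, path = tempfile(fileext = ".bedgraph")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}

# random non-overlapping sorted intervals within a region
random_intervals <- function(region, n = 10, gap_prob = 0.3) {
  res <- region$resolution
  width <- region$end - region$start
  cuts <- sort(sample(seq(region$start + 1, region$end - 1), 2 * n))
  starts <- cuts[seq(1, 2 * n, 2)]
  ends <- cuts[seq(2, 2 * n, 2)]
  keep <- ends > starts & stats::runif(n) > gap_prob
  data.frame(chrom = region$chrom, start = starts[keep],
             end = ends[keep],
             value = round(stats::runif(sum(keep), 0, 10), 3))
}

random_layer <- function(n, rgb = NULL, seed_alpha = NULL) {
  if (is.null(rgb)) rgb <- sample(0:255, 3, replace = TRUE)
  a <- matrix(sample(0:255, n * n, replace = TRUE), n, n)
  color_layer(rgb, a, label = paste0("L", paste(rgb, collapse = "-")))
}

unit_contacts <- function(values, region) {
  contact_matrix(values, region, "unit-scaled")
}

small_scene <- function(seed = 11, dispersion = 0.05) {
  make_scene(scene_spec(seed = seed, dispersion = dispersion))
}

# naive per-pixel / per-layer blending oracle (spec formulas verbatim)
blend_oracle <- function(layers) {
  n1 <- nrow(layers[[1]]$alpha); n2 <- ncol(layers[[1]]$alpha)
  rgbs <- array(0, c(n1, n2, 3)); alpha <- matrix(0L, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    total <- sum(vapply(layers, function(l) l$alpha[i, j], 0L))
    if (total == 0) {
      rgbs[i, j, ] <- 255
      alpha[i, j] <- 0L
    } else {
      mix <- c(0, 0, 0)
      for (l in layers)  # blend_ratio_b = alpha_b / total_alpha
        mix <- mix + l$rgb * l$alpha[i, j]
      mix <- mix / total
      rgbs[i, j, ] <- sign(mix) * floor(abs(mix) + 0.5)
      alpha[i, j] <- min(total, 255L)
    }
  }
  list(rgb = rgbs, alpha = alpha)
}

# two-sided Monte-Carlo permutation rank-sum oracle
perm_ranksum_p <- function(x, y, n_perm = 4000) {
  pooled <- c(x, y)
  nx <- length(x)
  obs <- sum(rank(pooled)[seq_len(nx)])
  null <- replicate(n_perm, {
    idx <- sample(length(pooled), nx)
    sum(rank(pooled)[idx])
  })
  mu <- mean(null)
  (sum(abs(null - mu) >= abs(obs - mu) - 1e-9) + 1) / (n_perm + 1)
}
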