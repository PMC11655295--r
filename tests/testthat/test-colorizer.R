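test_that("compose_layer applies the 8-bit conversion formula", {
  r <- tiny_region(2)
  ones <- unit_contacts(matrix(1, 2, 2), r)
  m1 <- new_signal_matrix(matrix(1, 2, 2))
  expect_true(all(compose_layer(m1, ones, "red")$alpha == 255))
  m0 <- new_signal_matrix(matrix(0, 2, 2))
  expect_true(all(compose_layer(m0, ones, "red")$alpha == 0))
  mh <- new_signal_matrix(matrix(0.5, 2, 2))
  ch <- unit_contacts(matrix(0.5, 2, 2), r)
  # scalar oracle: round-half-away(0.5 * 0.5 * 1 * 255) = round(63.75)
  expect_true(all(compose_layer(mh, ch, "red")$alpha == 64))
  expect_true(all(compose_layer(mh, ch, "red", 0.5)$alpha ==
                  floor(0.25 * 0.5 * 255 + 0.5)))
})

test_that("compose_layer matches the scalar formula on random pixels", {
  set.seed(20)
  for (rep in 1:10) {
    n <- sample(2:32, 1)
    r <- tiny_region(n)
    mv <- matrix(stats::runif(n * n), n)
    mv <- (mv + t(mv)) / 2
    cv <- matrix(stats::runif(n * n), n)
    cv <- (cv + t(cv)) / 2
    st <- stats::runif(1)
    lay <- compose_layer(new_signal_matrix(mv), unit_contacts(cv, r),
                         "#336699", overlay_strength = st)
    oracle <- matrix(0L, n, n)
    for (i in 1:n) for (j in 1:n)
      oracle[i, j] <- as.integer(floor(mv[i, j] * cv[i, j] * st * 255 + 0.5))
    expect_identical(lay$alpha, oracle)
  }
})

test_that("missing pixels become fully transparent", {
  r <- tiny_region(2)
  mv <- matrix(c(NA, 1, 1, 1), 2)
  lay <- compose_layer(new_signal_matrix(mv),
                       unit_contacts(matrix(1, 2, 2), r), "red")
  expect_equal(lay$alpha, matrix(c(0L, 255L, 255L, 255L), 2))
  expect_error(compose_layer(new_signal_matrix(matrix(1, 2, 2)),
                             unit_contacts(matrix(1, 3, 3), tiny_region(3)),
                             "red"), "dimensions differ")
  expect_error(compose_layer(new_signal_matrix(matrix(1, 2, 2)),
                             contact_matrix(matrix(1, 2, 2), r, "raw"),
                             "red"), "unit-scaled")
})

test_that("single and degenerate blends are identities", {
  l <- random_layer(6, rgb = c(200, 10, 50))
  b <- blend_layers(list(l))
  vis <- l$alpha > 0
  for (ch in 1:3)
    expect_true(all(b$rgb_channels[, , ch][vis] == l$rgb[ch]))
  expect_equal(b$alpha, l$alpha)
  # adding an all-transparent layer changes nothing
  empty <- color_layer(c(0, 255, 0), matrix(0L, 6, 6), "empty")
  b2 <- blend_layers(list(l, empty))
  expect_equal(b2$rgb_channels[, , 1][vis], b$rgb_channels[, , 1][vis])
  expect_equal(b2$alpha, b$alpha)
  expect_error(blend_layers(list()), "at least one layer")
})

test_that("equal red and blue alphas mix to the midpoint", {
  red <- color_layer(c(255, 0, 0), matrix(100L, 2, 2), "red")
  blue <- color_layer(c(0, 0, 255), matrix(100L, 2, 2), "blue")
  b <- blend_layers(list(red, blue))
  expect_true(all(b$rgb_channels[, , 1] == 128))  # round(127.5) half away
  expect_true(all(b$rgb_channels[, , 3] == 128))
  expect_true(all(b$rgb_channels[, , 2] == 0))
  expect_true(all(b$alpha == 200))
})

test_that("blending matches the naive per-pixel oracle and ignores order", {
  set.seed(33)
  for (rep in 1:8) {
    n <- sample(c(8, 16, 32), 1)
    k <- sample(2:5, 1)
    layers <- lapply(seq_len(k), function(i) random_layer(n))
    b <- blend_layers(layers)
    o <- blend_oracle(layers)
    expect_identical(b$alpha, o$alpha)
    expect_equal(b$rgb_channels, o$rgb, tolerance = 0)
    perm <- sample(k)
    b2 <- blend_layers(layers[perm])
    expect_identical(b2$rgb_channels, b$rgb_channels)
    expect_identical(b2$alpha, b$alpha)
  }
})

test_that("mixed channels stay within the contributing colors' hull", {
  set.seed(34)
  layers <- lapply(1:4, function(i) random_layer(12))
  b <- blend_layers(layers)
  for (i in 1:12) for (j in 1:12) {
    contrib <- Filter(function(l) l$alpha[i, j] > 0, layers)
    if (length(contrib) == 0) next
    for (ch in 1:3) {
      chs <- vapply(contrib, function(l) l$rgb[ch], 0L)
      expect_gte(b$rgb_channels[i, j, ch], min(chs) - 1)
      expect_lte(b$rgb_channels[i, j, ch], max(chs) + 1)
    }
  }
  expect_true(all(b$alpha <= 255))
})

test_that("n copies of a layer keep its hue and clip the summed alpha", {
  l <- random_layer(10, rgb = c(40, 90, 200))
  for (k in c(2, 3, 5)) {
    b <- blend_layers(rep(list(l), k))
    vis <- l$alpha > 0
    expect_true(all(b$rgb_channels[, , 1][vis] == 40))
    expect_true(all(b$rgb_channels[, , 3][vis] == 200))
    expect_equal(b$alpha, pmin(k * l$alpha, 255L))
  }
})

test_that("eigen layers split sign into disjoint same-sign supports", {
  r <- tiny_region(4)
  cs <- unit_contacts(matrix(1, 4, 4), r)
  eig <- binned_track(c(2, 1, -1, -2), r, name = "eig", signed = TRUE)
  ab <- eigen_layers(eig, cs)
  a_sup <- ab$A$alpha > 0
  b_sup <- ab$B$alpha > 0
  # brute-force sign enumeration: support is exactly the same-sign blocks
  expect_equal(a_sup, outer(1:4 %in% 1:2, 1:4 %in% 1:2, `&`))
  expect_equal(b_sup, outer(1:4 %in% 3:4, 1:4 %in% 3:4, `&`))
  expect_true(all(a_sup[1:2, 1:2]))
  expect_true(all(b_sup[3:4, 3:4]))
  expect_false(any(a_sup & b_sup))
  # all-positive: B layer fully transparent
  pos <- binned_track(c(1, 2, 3, 4), r, name = "p", signed = TRUE)
  expect_true(all(eigen_layers(pos, cs)$B$alpha == 0))
  # zero eigenvalue bin is transparent in both layers
  z <- binned_track(c(0, 2, -2, 1), r, name = "z", signed = TRUE)
  lz <- eigen_layers(z, cs)
  expect_true(all(lz$A$alpha[1, ] == 0) && all(lz$A$alpha[, 1] == 0))
  expect_true(all(lz$B$alpha[1, ] == 0) && all(lz$B$alpha[, 1] == 0))
  expect_error(eigen_layers(binned_track(1:4, r), cs), "signed")
})

test_that("eigen supports respect the sign-enumeration oracle", {
  set.seed(35)
  for (rep in 1:10) {
    n <- 12
    r <- tiny_region(n)
    v <- stats::runif(n, -1, 1)
    v[sample(n, 2)] <- 0
    cs <- unit_contacts(matrix(stats::runif(n * n, 0.5, 1), n) * 0 + 1, r)
    lay <- eigen_layers(binned_track(v, r, name = "e", signed = TRUE), cs)
    a_sup <- lay$A$alpha > 0
    b_sup <- lay$B$alpha > 0
    expect_false(any(a_sup & b_sup))
    same_pos <- outer(v > 0, v > 0, `&`)
    same_neg <- outer(v < 0, v < 0, `&`)
    expect_true(all(!a_sup | same_pos))
    expect_true(all(!b_sup | same_neg))
  }
})

test_that("chromHMM bins go to the largest-overlap state, first-seen ties", {
  r <- tiny_region(4, res = 100)
  seg <- chromhmm_segmentation(data.frame(
    chrom = "chrT", start = c(0, 130, 250), end = c(130, 250, 400),
    state = c("S1", "S2", "S1"),
    r = c(255, 0, 255), g = c(0, 255, 0), b = c(0, 0, 0)))
  asg <- assign_chromhmm_bins(seg, r)
  expect_equal(asg, c("S1", "S2", "S1", "S1"))
  # exact 50/50 tie goes to the first-seen state
  seg2 <- chromhmm_segmentation(data.frame(
    chrom = "chrT", start = c(0, 50), end = c(50, 400),
    state = c("Late", "Early"), r = c(1, 2), g = c(1, 2), b = c(1, 2)))
  expect_equal(assign_chromhmm_bins(seg2, r)[1], "Late")
})

test_that("chromHMM bin assignment matches a per-base majority oracle", {
  set.seed(36)
  r <- tiny_region(20, res = 50)
  cuts <- sort(sample(seq(10, r$end - 10, 10), 14))
  edges <- c(0, cuts, r$end)
  states <- paste0("E", sample(1:15, length(edges) - 1, replace = TRUE))
  cols <- t(sapply(seq_along(states), function(i) (i * c(17, 29, 43)) %% 256))
  seg <- chromhmm_segmentation(data.frame(
    chrom = "chrT", start = edges[-length(edges)], end = edges[-1],
    state = states, r = cols[, 1], g = cols[, 2], b = cols[, 3]))
  asg <- assign_chromhmm_bins(seg, r)
  # per-base oracle with first-seen tie-break
  first_seen <- unique(states)
  for (b in seq_len(20)) {
    lo <- (b - 1) * 50; hi <- b * 50
    base <- character(50)
    for (k in seq_along(states)) {
      s <- max(edges[k], lo); e <- min(edges[k + 1], hi)
      if (e > s) base[(s - lo + 1):(e - lo)] <- states[k]
    }
    tab <- table(factor(base[nzchar(base)], levels = first_seen))
    expect_identical(asg[b], names(tab)[which.max(tab)])
  }
})

test_that("chromHMM layers use state colors and feed blending", {
  r <- tiny_region(4, res = 100)
  cs <- unit_contacts(matrix(0.5, 4, 4), r)
  # one state covering everything: alpha = contact-scaled everywhere
  seg <- chromhmm_segmentation(data.frame(
    chrom = "chrT", start = 0, end = 400, state = "All",
    r = 10, g = 20, b = 30))
  lays <- chromhmm_layers(seg, r, cs)
  expect_length(lays, 1)
  expect_true(all(lays[[1]]$alpha == 128))  # round(0.5*255)
  expect_equal(lays[[1]]$rgb, c(10L, 20L, 30L))
  # two non-adjacent states paint disjoint diagonal blocks
  seg2 <- chromhmm_segmentation(data.frame(
    chrom = "chrT", start = c(0, 100, 200, 300),
    end = c(100, 200, 300, 400),
    state = c("X", "mid", "Y", "mid"),
    r = c(255, 0, 0, 0), g = c(0, 128, 255, 128), b = c(0, 128, 0, 128)))
  lays2 <- chromhmm_layers(seg2, r, cs, states = c("X", "Y"))
  sup_x <- lays2[[1]]$alpha > 0
  sup_y <- lays2[[2]]$alpha > 0
  expect_false(any(sup_x & sup_y))
  expect_true(sup_x[1, 1] && sup_y[3, 3])
  expect_error(chromhmm_layers(seg2, r, cs, states = "nope"), "absent")
})
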