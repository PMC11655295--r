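test_that("dense text matrices read through identically and symmetrically", {
  r <- tiny_region(4)
  vals <- matrix(c(4, 3, 2, 1,
                   3, 5, 3, 2,
                   2, 3, 6, 3,
                   1, 2, 3, 7), 4, 4)
  f <- tempfile()
  writeLines(apply(vals, 1, paste, collapse = " "), f)
  cm <- read_contact_matrix(f, r)
  expect_equal(cm$values, vals)
  expect_identical(cm$values, t(cm$values))
  expect_identical(cm$normalization_tag, "raw")
})

test_that("unsnapped regions are snapped and reported by the reader", {
  vals <- matrix(1, 3, 3)
  f <- tempfile()
  writeLines(apply(vals, 1, paste, collapse = " "), f)
  r <- list(chrom = "chrT", start = 50, end = 250, resolution = 100)
  class(r) <- "genomic_region"
  cm <- read_contact_matrix(f, r)
  expect_equal(cm$region$start, 0)
  expect_equal(cm$region$end, 300)
  expect_equal(n_bins(cm$region), 3L)
})

test_that("malformed and missing contact sources are rejected", {
  f <- tempfile()
  writeLines(c("1 2 3", "4 5 6"), f)  # non-square
  expect_error(read_contact_matrix(f, tiny_region(2)), "not square")
  expect_error(read_contact_matrix(tempfile(), tiny_region(2)),
               "no such file")
  f2 <- tempfile()
  writeLines(c("1 2", "2 1"), f2)
  expect_error(read_contact_matrix(f2, tiny_region(4)), "bins")
})

test_that("bedGraph binning is the coverage-weighted mean with NA gaps", {
  r <- tiny_region(5, res = 100)
  # one interval exactly one bin wide; neighbors untouched
  f <- write_bedgraph_file(data.frame("chrT", 100, 200, 7))
  tr <- read_track(f, r)
  expect_equal(tr$values, c(NA, 7, NA, NA, NA))
  # half a bin at 4, other half at 0 -> mean 2
  f2 <- write_bedgraph_file(data.frame(chrom = "chrT",
                                       start = c(200, 250),
                                       end = c(250, 300),
                                       value = c(4, 0)))
  expect_equal(read_track(f2, r)$values[3], 2)
})

test_that("random bedGraphs match the per-base oracle", {
  r <- tiny_region(12, res = 50)
  set.seed(101)
  for (rep in 1:5) {
    df <- random_intervals(r, n = 8)
    f <- write_bedgraph_file(df)
    tr <- read_track(f, r)
    oracle <- per_base_bin_oracle(df$start, df$end, df$value, r)
    expect_equal(tr$values, oracle, tolerance = 1e-9)
  }
})

test_that("unsorted or overlapping bedGraphs are rejected with a message", {
  r <- tiny_region(4)
  f <- write_bedgraph_file(data.frame(chrom = "chrT",
                                      start = c(200, 0),
                                      end = c(300, 100),
                                      value = c(1, 2)))
  expect_error(read_track(f, r), "unsorted or overlapping")
  f2 <- write_bedgraph_file(data.frame(chrom = "chrT",
                                       start = c(0, 50),
                                       end = c(100, 150),
                                       value = c(1, 2)))
  expect_error(read_track(f2, r), "unsorted or overlapping")
  f3 <- write_bedgraph_file(data.frame("chrQ", 0, 100, 1))
  expect_error(read_track(f3, r), "chromosome chrT not in")
})

test_that("BED files become unit tracks with 0 (not NA) background", {
  r <- tiny_region(6, res = 100)
  f <- tempfile(fileext = ".bed")
  writeLines("chrT\t200\t400", f)  # spans bins 3-4 entirely
  tr <- bed_to_track(f, r)
  expect_equal(tr$values, c(0, 0, 1, 1, 0, 0))
  # empty BED -> all zeros
  f2 <- tempfile(fileext = ".bed"); writeLines(character(), f2)
  expect_equal(bed_to_track(f2, r)$values, rep(0, 6))
  # 25% of a bin covered -> 0.25
  f3 <- tempfile(fileext = ".bed"); writeLines("chrT\t0\t25", f3)
  expect_equal(bed_to_track(f3, r)$values[1], 0.25)
  f4 <- tempfile(fileext = ".bed"); writeLines("chrT\t100", f4)
  expect_error(bed_to_track(f4, r), "malformed BED")
})

test_that("bed_to_track agrees with read_track on the value-1 bedGraph", {
  # agreement holds wherever coverage is bin-aligned; inside a partially
  # covered bin the BED reading is the covered fraction (presence), while
  # the bedGraph mean over covered bases is 1
  r <- tiny_region(10, res = 100)
  set.seed(7)
  edges <- sort(sample(seq(0, 1000, 100), 8))
  iv <- data.frame(start = edges[c(1, 3, 5)], end = edges[c(2, 4, 6)])
  iv <- iv[iv$end > iv$start, ]
  bed <- tempfile(fileext = ".bed")
  writeLines(sprintf("chrT\t%d\t%d", iv$start, iv$end), bed)
  bg <- write_bedgraph_file(data.frame("chrT", iv$start, iv$end, 1))
  a <- bed_to_track(bed, r)$values
  b <- read_track(bg, r)$values
  covered <- !is.na(b)
  expect_equal(a[covered], b[covered])
  expect_true(all(a[!covered] == 0))
})

test_that("binning is conservative for fully covered regions", {
  r <- tiny_region(8, res = 100)
  # tile the region completely with random values
  set.seed(21)
  edges <- sort(c(r$start, r$end, sample(seq(50, 750, 50), 6)))
  df <- data.frame(chrom = "chrT", start = edges[-length(edges)],
                   end = edges[-1],
                   value = round(stats::runif(length(edges) - 1), 3))
  f <- write_bedgraph_file(df)
  tr <- read_track(f, r)
  expect_equal(sum(tr$values * r$resolution),
               sum(df$value * (df$end - df$start)), tolerance = 1e-9)
})

test_that("chromHMM BED9 parses, clips, and orders states first-seen", {
  r <- tiny_region(5, res = 100)
  f <- tempfile(fileext = ".bed")
  writeLines(c(
    "chrT\t0\t150\tEnh\t0\t.\t0\t150\t255,255,0",
    "chrT\t150\t300\tQui\t0\t.\t150\t300\t200,200,200",
    "chrT\t300\t600\tEnh\t0\t.\t300\t600\t255,255,0"), f)
  seg <- read_chromhmm(f, r)
  expect_equal(seg$states$state, c("Enh", "Qui"))
  expect_equal(unlist(seg$states[1, c("r", "g", "b")], use.names = FALSE),
               c(255, 255, 0))
  # straddling interval clipped to the region
  expect_equal(max(seg$intervals$end), 500)
  f2 <- tempfile(fileext = ".bed")
  writeLines("chrT\t0\t100\tX\t0\t.\t0\t100\tnotacolor", f2)
  expect_error(read_chromhmm(f2, r), "itemRgb")
})

test_that("reading a source twice is deterministic", {
  r <- tiny_region(6)
  set.seed(3)
  df <- random_intervals(r, 5)
  f <- write_bedgraph_file(df)
  expect_identical(read_track(f, r)$values, read_track(f, r)$values)
})

test_that("cooler and bigWig fixtures round-trip against in-memory data", {
  sc <- make_scene(scene_spec(seed = 5, dispersion = 0.05),
                   dir = file.path(tempdir(), "rt-scene"))
  cm <- read_contact_matrix(sc$files$cool, sc$region)
  expect_equal(cm$values, sc$contacts$values)
  tr <- read_track(sc$files$H3K9me3_bw, sc$region)
  expect_equal(tr$values, sc$tracks$H3K9me3$values, tolerance = 1e-6)
  tr2 <- read_track(sc$files$H3K9me3_bedgraph, sc$region)
  expect_equal(tr2$values, sc$tracks$H3K9me3$values, tolerance = 1e-12)
  seg <- read_chromhmm(sc$files$segmentation, sc$region)
  expect_equal(seg$intervals$state, sc$segmentation$intervals$state)
  expect_equal(seg$states, sc$segmentation$states)
})

test_that("cooler balancing weights apply and NaN weights become NA", {
  r <- tiny_region(4, res = 100)
  vals <- outer(1:4, 1:4, function(i, j) abs(i - j) + 1)
  cm <- contact_matrix(vals, r, "raw")
  f <- tempfile(fileext = ".cool")
  w <- c(0.5, 1, 2, NaN)
  write_cooler(cm, f, weights = w)
  raw <- read_contact_matrix(f, r, balance = FALSE)
  expect_equal(raw$values, vals)
  bal <- read_contact_matrix(f, r, balance = TRUE)
  expect_equal(bal$values[1:3, 1:3], vals[1:3, 1:3] * outer(w[1:3], w[1:3]))
  expect_true(all(is.na(bal$values[4, ])))
  expect_identical(bal$normalization_tag, "balanced")
})
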