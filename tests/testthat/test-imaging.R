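# Core image operators: calibrated I/O, Otsu thresholding, labelling,
# watershed dissection, distance transforms and mask cleanup.

test_that("images are rescaled by source bit depth and round-trip", {
  tmp8 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 8, 8), tmp8)
  g <- read_image(tmp8, pixel_size_mm = 0.01)
  expect_s3_class(g, "intensity_grid")
  expect_true(all(g$pixels == 1))
  expect_identical(g$pixel_size_mm, 0.01)
  expect_identical(g$bit_depth_src, 8L)

  tmp16 <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0, 6, 9), tmp16, bits.per.sample = 16L)
  g16 <- read_image(tmp16, 0.02)
  expect_true(all(g16$pixels == 0))
  expect_identical(dim(g16$pixels), c(6L, 9L))
  expect_identical(g16$bit_depth_src, 16L)

  # 8-bit grey level 51 -> 51/255 = 0.2 exactly
  png::writePNG(matrix(51 / 255, 4, 4), tmp8)
  expect_equal(read_image(tmp8, 1)$pixels[1, 1], 0.2)

  # round trip within one quantum of the target bit depth
  x <- matrix(runif(96), 12, 8)
  write_image(intensity_grid(x, 0.01), tmp8)
  expect_lt(max(abs(read_image(tmp8, 0.01)$pixels - x)), 1 / 255)
  write_image(x, tmp16, bits = 16L)
  expect_lt(max(abs(read_image(tmp16, 0.01)$pixels - x)), 1 / 65535)
})

test_that("multi-channel and unreadable inputs are rejected", {
  tmp <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(48), c(4, 4, 3)), tmp)
  expect_error(read_image(tmp, 0.01), "multi-channel")
  expect_error(read_image(file.path(tempdir(), "nope.png"), 0.01),
               "no such file")
  expect_error(intensity_grid(matrix(2, 4, 4), 0.01), "\\[0, 1\\]")
  expect_error(intensity_grid(matrix(0.5, 4, 4), -1), "positive")
})

test_that("Otsu threshold separates a two-level image and rejects constants", {
  m <- matrix(c(rep(0.1, 120), rep(0.9, 136)), 16, 16)
  t <- otsu_threshold(m)
  expect_gt(t, 0.1)
  expect_lt(t, 0.9)
  expect_error(otsu_threshold(matrix(0.5, 8, 8)), "degenerate")
})

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  set.seed(42)
  for (i in 1:50) {
    v <- switch(1 + i %% 3,
                runif(256),
                c(rnorm(128, 0.3, 0.05), rnorm(128, 0.7, 0.08)),
                sample(seq(0, 1, length.out = 17), 256, replace = TRUE))
    v <- pmin(pmax(v, 0), 1)
    m <- matrix(v, 16, 16)
    expect_equal(otsu_threshold(m), oracle_otsu(v), tolerance = 1e-12)
  }
  # and for a non-default bin count
  set.seed(7)
  v <- runif(256)
  expect_equal(otsu_threshold(matrix(v, 16, 16), n_bins = 64L),
               oracle_otsu(v, n_bins = 64L), tolerance = 1e-12)
})

test_that("connected components respect connectivity and match flood fill", {
  empty <- matrix(FALSE, 5, 5)
  expect_identical(attr(connected_components(empty), "n_labels"), 0L)

  diagpair <- matrix(FALSE, 4, 4)
  diagpair[2, 2] <- diagpair[3, 3] <- TRUE
  expect_identical(attr(connected_components(diagpair, 8L), "n_labels"), 1L)
  expect_identical(attr(connected_components(diagpair, 4L), "n_labels"), 2L)

  set.seed(11)
  for (i in 1:10) {
    mask <- matrix(runif(144) < 0.4, 12, 12)
    for (conn in c(4L, 8L)) {
      got <- connected_components(mask, conn)
      want <- oracle_flood_fill(mask, conn)
      expect_identical(matrix(as.integer(got), 12, 12),
                       matrix(as.integer(want), 12, 12))
    }
  }
})

test_that("watershed splits touching discs and partitions the mask", {
  # single filled disc stays one object
  disc <- make_disc(60, r = 20)
  w1 <- watershed_split(disc)
  expect_identical(attr(w1, "n_labels"), 1L)
  expect_identical(w1 > 0L, disc)

  # two discs r=20, centers 30 px apart: 2 labels, areas sum exactly,
  # each within 10% of one disc's area
  two <- make_disc(80, cy = 40, cx = 25, r = 20) |
    make_disc(80, cy = 40, cx = 55, r = 20)
  w2 <- watershed_split(two)
  expect_identical(attr(w2, "n_labels"), 2L)
  areas <- tabulate(w2[w2 > 0L], nbins = 2L)
  expect_identical(sum(areas), sum(two))
  one_disc <- sum(make_disc(60, r = 20))
  expect_true(all(abs(areas - one_disc) / one_disc < 0.10))

  # empty mask
  w0 <- watershed_split(matrix(FALSE, 10, 10))
  expect_identical(attr(w0, "n_labels"), 0L)

  # partition property on random blobby masks
  set.seed(5)
  for (i in 1:5) {
    mask <- EBImage::dilate(matrix(runif(900) < 0.02, 30, 30),
                            EBImage::makeBrush(5, "disc")) > 0
    if (!any(mask)) next
    w <- watershed_split(mask)
    expect_identical(w > 0L, mask)                    # union = mask
    n <- attr(w, "n_labels")
    expect_gte(n, attr(connected_components(mask), "n_labels"))
    expect_setequal(unique(as.integer(w[w > 0])), seq_len(n))
  }
})

test_that("distance transform matches geometry and is 1-Lipschitz", {
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(distance_to_boundary(single)[3, 3], 1.0)

  disc <- make_disc(61, r = 25)
  d <- distance_to_boundary(disc)
  expect_lt(abs(d[31, 31] - 25), 0.5 + 1e-9)
  expect_true(all(d[!disc] == 0))

  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0)
  dcb <- distance_to_boundary(cb)
  expect_true(all(dcb[cb] == 1.0))

  expect_error(distance_to_boundary(matrix(TRUE, 4, 4)), "degenerate")
  expect_error(distance_to_boundary(matrix(FALSE, 4, 4)), "degenerate")

  # 1-Lipschitz between 4-neighbours
  set.seed(3)
  mask <- EBImage::dilate(matrix(runif(400) < 0.05, 20, 20),
                          EBImage::makeBrush(5, "disc")) > 0
  if (any(mask) && !all(mask)) {
    dd <- distance_to_boundary(mask)
    expect_lte(max(abs(diff(dd))), 1 + 1e-9)          # row direction
    expect_lte(max(abs(diff(t(dd)))), 1 + 1e-9)       # column direction
  }
})

test_that("mask cleanup fills holes and keeps the largest component", {
  annulus <- make_disc(40, r = 15) & !make_disc(40, r = 8)
  expect_identical(fill_holes_and_largest(annulus), make_disc(40, r = 15))

  two <- make_disc(60, cy = 20, cx = 20, r = 6) |
    make_disc(60, cy = 45, cx = 45, r = 4)
  kept <- fill_holes_and_largest(two)
  expect_identical(kept, make_disc(60, cy = 20, cx = 20, r = 6))

  one <- matrix(FALSE, 5, 5); one[2, 4] <- TRUE
  expect_identical(fill_holes_and_largest(one), one)
  expect_error(fill_holes_and_largest(matrix(FALSE, 4, 4)), "empty")
})

test_that("YAML config round-trips analysis parameters", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pixel_size_mm: 0.01", "otsu_bins: 256",
               "edge_depth_px: 50"), tmp)
  cfg <- load_config(tmp)
  expect_identical(cfg$pixel_size_mm, 0.01)
  expect_identical(cfg$edge_depth_px, 50L)
})
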