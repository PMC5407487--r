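test_that("z-projection honors its method and matches a per-pixel oracle", {
  plane <- matrix(1:12, 3, 4)
  expect_identical(project_stack(array(plane, c(3, 4, 1)), "max"), plane)
  two <- array(c(matrix(3, 2, 2), matrix(7, 2, 2)), c(2, 2, 2))
  expect_identical(project_stack(two, "max"), matrix(7, 2, 2))
  set.seed(6)
  st <- array(runif(4 * 4 * 3), c(4, 4, 3))
  means <- matrix(0, 4, 4)
  for (r in 1:4) for (c in 1:4) means[r, c] <- mean(st[r, c, ])
  expect_equal(project_stack(st, "mean"), means, tolerance = 1e-12)
})

test_that("background subtraction thresholds at the control level", {
  img <- matrix(c(2, 5, 9, 7), 2, 2)
  expect_identical(subtract_background(img, 0), img)
  expect_identical(subtract_background(matrix(5, 3, 3), 5),
                   matrix(0, 3, 3))
  expect_identical(subtract_background(img, 4), matrix(c(0, 1, 5, 3), 2, 2))
  expect_error(subtract_background(img, -1), "non-negative")
  # idempotence: thresholding twice at the same level changes nothing
  once <- subtract_background(img, 3)
  expect_identical(subtract_background(once, 0), once)
  expect_identical(pmax(once - 0, 0), once)
})

test_that("control level summarizes the ROI with the requested statistic", {
  img <- matrix(8.5, 10, 10)
  roi <- roi_mask(cbind(c(1, 9, 9, 1), c(1, 1, 9, 9)))
  expect_equal(control_level(img, roi, "mean"), 8.5)

  img2 <- matrix(0, 4, 10)
  img2[2, 3:6] <- c(1, 2, 3, 4)
  roi2 <- roi_mask(cbind(c(2, 6, 6, 2), c(1, 1, 2, 2)))  # row 2, cols 3:6
  expect_equal(control_level(img2, roi2, "mean"), 2.5)

  set.seed(10)
  img3 <- matrix(runif(400), 20, 20)
  roi3 <- roi_mask(cbind(c(2, 17, 17, 2), c(2, 2, 17, 17)))
  vals <- sort(kymoclock:::roi_pixels(img3, roi3)$values)
  h <- (length(vals) - 1) * 0.95
  expected <- vals[floor(h) + 1] * (1 - (h - floor(h))) +
    vals[min(floor(h) + 2, length(vals))] * (h - floor(h))
  expect_equal(control_level(img3, roi3, "percentile", q = 95), expected,
               tolerance = 1e-12)

  tiny <- roi_mask(cbind(c(0.1, 0.3, 0.3, 0.1), c(0.1, 0.1, 0.3, 0.3)))
  expect_error(control_level(img3, tiny, "mean"), "no pixel")
})

test_that("extraction reproduces the per-pixel assignment oracle", {
  # two-region image: 10 posterior of coordinate 0.5, 20 anterior
  img <- matrix(0, 20, 40)
  img[, 1:20] <- 10
  img[, 21:40] <- 20
  roi <- roi_mask(cbind(c(0, 40, 40, 0), c(4, 4, 16, 16)))
  ax <- axis_spec(origin = c(0, 10),
                  polyline = rbind(c(0, 10), c(40, 10)), unit_length = 40)
  p <- extract_profile(img, roi, ax, n_bins = 4, channel = "test")
  oracle <- oracle_extract_rect(img, c(0, 40), c(4, 16), 0, 40, 4)
  expect_equal(p$intensities, oracle, tolerance = 1e-12)
  expect_equal(p$intensities, c(10, 10, 20, 20), tolerance = 1e-12)

  # constant image: every bin equals the constant
  cimg <- matrix(3.25, 20, 40)
  pc <- extract_profile(cimg, roi, ax, n_bins = 5)
  expect_equal(pc$intensities, rep(3.25, 5))

  # linearity: extracting image + c shifts every bin by c exactly
  p2 <- extract_profile(img + 1.75, roi, ax, n_bins = 4)
  expect_equal(p2$intensities, p$intensities + 1.75)

  # ROI entirely beyond unit length -> no admissible coordinate
  ax_short <- axis_spec(c(-80, 10), rbind(c(-80, 10), c(40, 10)),
                        unit_length = 30)
  expect_error(extract_profile(img, roi, ax_short, 4), "\\[0, 1\\]")
})

test_that("reversing the axis direction reverses the profile", {
  set.seed(3)
  img <- matrix(runif(20 * 40, 1, 2), 20, 40)
  roi <- roi_mask(cbind(c(0, 40, 40, 0), c(4, 4, 16, 16)))
  fwd <- axis_spec(c(0, 10), rbind(c(0, 10), c(40, 10)), 40)
  rev_ax <- axis_spec(c(40, 10), rbind(c(40, 10), c(0, 10)), 40)
  pf <- extract_profile(img, roi, fwd, n_bins = 8)
  pr <- extract_profile(img, roi, rev_ax, n_bins = 8)
  expect_equal(pr$intensities, rev(pf$intensities), tolerance = 1e-10)
})

test_that("empty interior bins are interpolated and flagged", {
  img <- matrix(5, 30, 30)
  # two disjoint ROI lobes leave a gap of empty bins in between
  roi <- roi_mask(cbind(c(0, 30, 30, 0), c(2, 2, 12, 12)))
  ax <- axis_spec(c(0, 6), rbind(c(0, 6), c(30, 6)), 90)
  # unit length 3x the image: only the first third of [0,1] has pixels
  p <- extract_profile(img, roi, ax, n_bins = 9)
  expect_gt(length(p$interpolated_bins), 0)
  expect_equal(p$intensities, rep(5, 9))  # nearest-value fill
})

test_that("profile normalization satisfies its contracts", {
  p <- spatial_profile("s", "c", c(0.1, 0.5, 0.9), c(2, 4, 8))
  pm <- normalize_profile(p, "max")
  expect_equal(pm$intensities, c(0.25, 0.5, 1))
  expect_true(pm$normalized)
  expect_equal(normalize_profile(pm, "max")$intensities, pm$intensities)

  set.seed(4)
  pos <- seq(0, 1, length.out = 33)
  pr <- spatial_profile("s", "c", pos, runif(33, 0.5, 3))
  pa <- normalize_profile(pr, "area")
  integ <- sum(diff(pos) * (pa$intensities[-1] + pa$intensities[-33]) / 2)
  expect_equal(integ, 1, tolerance = 1e-9)

  pz <- spatial_profile("s", "c", c(0, 1), c(0, 0))
  expect_error(normalize_profile(pz), "all-zero")
})

test_that("phase calls follow the band-centroid decision rule", {
  pos <- (seq_len(100) - 0.5) / 100
  band_at <- function(ctr) spatial_profile("s", "Lfng_i", pos,
    exp(-(pos - ctr)^2 / (2 * 0.05^2)))
  expect_identical(assign_phase(band_at(0.15))$phase, 1L)
  expect_identical(assign_phase(band_at(0.50))$phase, 2L)
  expect_identical(assign_phase(band_at(0.80))$phase, 3L)

  # bimodal: centroid must match an explicit weighted-mean oracle
  y <- 2 * exp(-(pos - 0.2)^2 / (2 * 0.04^2)) +
    exp(-(pos - 0.7)^2 / (2 * 0.04^2))
  p <- spatial_profile("s", "Lfng_i", pos, y)
  call <- assign_phase(p, threshold_fraction = 0.3)
  band <- y >= 0.3 * max(y)
  expect_equal(call$centroid, sum(pos[band] * y[band]) / sum(y[band]),
               tolerance = 1e-12)
  expect_identical(call$phase,
                   if (call$centroid < 1 / 3) 1L
                   else if (call$centroid < 2 / 3) 2L else 3L)
  expect_equal(call$width, mean(band))

  pz <- spatial_profile("s", "c", c(0, 1), c(0, 0))
  expect_error(assign_phase(pz), "positive")
})

test_that("matrix assembly resamples exactly and validates its inputs", {
  pos7 <- seq(0.05, 0.95, length.out = 7)
  set.seed(12)
  y7 <- runif(7, 1, 3)
  p <- spatial_profile("a", "c", pos7, y7)
  m <- build_matrix(list(p), n_bins = 10)
  expect_equal(m$values[, 1],
               pmax(oracle_lininterp(pos7, y7, (1:10 - 0.5) / 10), 0),
               tolerance = 1e-12)

  # exactness on affine profiles, arbitrary grid pair
  aff <- function(x) 2 + 3 * x
  pa <- spatial_profile("a", "c", pos7, aff(pos7))
  pb <- spatial_profile("b", "c", seq(0.2, 0.8, length.out = 5),
                        aff(seq(0.2, 0.8, length.out = 5)))
  ma <- build_matrix(list(pa, pb), n_bins = 13)
  centers <- (1:13 - 0.5) / 13
  expect_equal(ma$values[, 1], aff(centers), tolerance = 1e-12)
  expect_equal(ma$values[, 2], aff(centers), tolerance = 1e-12)

  # a profile already on the target grid passes through unchanged
  centers10 <- (1:10 - 0.5) / 10
  pg <- spatial_profile("g", "c", centers10, runif(10, 1, 2))
  expect_equal(build_matrix(list(pg), 10)$values[, 1], pg$intensities)

  c1 <- spatial_profile("a", "c", centers10, rep(1.5, 10))
  c2 <- spatial_profile("b", "c", centers10, rep(2.5, 10))
  mc <- build_matrix(list(c1, c2), 10)
  expect_equal(unname(mc$values), cbind(rep(1.5, 10), rep(2.5, 10)))

  other <- spatial_profile("x", "other", centers10, rep(1, 10))
  expect_error(build_matrix(list(c1, other), 10), "channel")
  dup <- spatial_profile("a", "c", centers10, rep(1, 10))
  expect_error(build_matrix(list(c1, dup), 10), "duplicate")
  norm <- normalize_profile(c1, "max")
  expect_error(build_matrix(list(norm, c2), 10), "normalized")
})
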