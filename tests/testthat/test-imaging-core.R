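test_that("constructors enforce calibration and geometry invariants", {
  expect_error(calibrated_image(matrix(1, 2, 2), 0), "positive")
  expect_error(calibrated_image(matrix(-1, 2, 2), 0.1), "non-negative")
  img <- make_image(matrix(1, 4, 4))
  expect_error(time_lapse(list(img, img), c(0, 0)), "increasing")
  expect_error(time_lapse(list(img, make_image(matrix(1, 5, 4))), c(0, 1)),
               "unequal")
  expect_error(circle_roi(point_roi(1, 1), 0), "positive")
})

test_that("circular ROI mean follows the pixel-center rule", {
  img <- make_image(matrix(7, 31, 31))
  expect_equal(roi_mean_intensity(img, circle_roi(point_roi(15, 15), 0.5)), 7)

  # half-plane: 0 for x <= 15, 10 for x >= 16; circle centered on the edge
  m <- matrix(0, 31, 31); m[, 17:31] <- 10
  img2 <- make_image(m)
  roi <- circle_roi(point_roi(15.5, 15), 0.8)
  # brute-force pixel enumeration oracle
  g <- expand.grid(x = 0:30, y = 0:30)
  keep <- (g$x - 15.5)^2 + (g$y - 15)^2 <= 8^2
  expect_equal(roi_mean_intensity(img2, roi), mean(m[cbind(g$y + 1, g$x + 1)][keep]))
  expect_lt(abs(roi_mean_intensity(img2, roi) - 5), 0.5)

  # circle too small to contain any pixel center
  expect_error(roi_mean_intensity(img, circle_roi(point_roi(15.5, 15.5), 0.04)),
               "no pixel centers")
  expect_error(roi_mean_intensity(img, circle_roi(point_roi(1, 1), 2)),
               "beyond")
})

test_that("ROI mean and background-subtracted mean respect offset linearity", {
  set.seed(42)
  m <- matrix(runif(31 * 31, 1, 5), 31, 31)
  roi <- circle_roi(point_roi(15, 15), 0.9)
  base <- roi_mean_intensity(make_image(m), roi)
  expect_equal(roi_mean_intensity(make_image(m + 3), roi), base + 3)

  mask <- matrix(FALSE, 31, 31); mask[5:10, 5:10] <- TRUE
  bg <- matrix(FALSE, 31, 31); bg[20:25, 20:25] <- TRUE
  v0 <- background_subtracted_mean(make_image(m), mask, bg)
  v1 <- background_subtracted_mean(make_image(m + 3), mask, bg)
  expect_equal(v1, v0)
})

test_that("background-subtracted mean equals the difference of the two means", {
  set.seed(7)
  m <- matrix(runif(400, 10, 200), 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[3:8, 3:8] <- TRUE
  bg <- matrix(FALSE, 20, 20); bg[15:19, 15:19] <- TRUE
  img <- make_image(m)
  expect_equal(background_subtracted_mean(img, mask, bg),
               mean(m[mask]) - mean(m[bg]))
  # integrated-density identity on a constructed case: mask mean 120, bg 20
  m2 <- matrix(20, 20, 20); m2[mask] <- 120
  expect_equal(background_subtracted_mean(make_image(m2), mask, bg), 100)
  expect_equal(background_subtracted_mean(make_image(m2 * 0 + 20), mask, bg), 0)
  expect_error(background_subtracted_mean(img, mask & FALSE, bg), "empty")
  expect_error(background_subtracted_mean(img, mask, mask), "disjoint")
})

test_that("line profiles interpolate bilinearly and report um positions", {
  ramp <- matrix(rep(0:30, each = 31), 31, 31)  # column-major: I(x, y) = x
  img <- make_image(ramp * 1.0, pixel_size = 0.2)
  prof <- sample_line_profile(img, point_roi(2, 10), point_roi(28, 10))
  expect_equal(prof$intensity, seq(2, 28))
  expect_equal(prof$position_um, (0:26) * 0.2)

  # reversal symmetry at non-integer endpoints
  set.seed(11)
  m <- matrix(runif(31 * 31), 31, 31)
  img2 <- make_image(m)
  p1 <- point_roi(3.3, 4.7); p2 <- point_roi(26.1, 22.9)
  fwd <- sample_line_profile(img2, p1, p2)
  bwd <- sample_line_profile(img2, p2, p1)
  expect_equal(fwd$intensity, rev(bwd$intensity), tolerance = 1e-12)
  expect_error(sample_line_profile(img2, p1, p1), "degenerate")
  expect_error(sample_line_profile(img2, p1, point_roi(40, 4)), "inside")
})

test_that("diagonal profile across a Gaussian spot matches the analytic values", {
  n <- 101; c0 <- 50; s <- 6
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  img <- make_image(exp(-((x - c0)^2 + (y - c0)^2) / (2 * s^2)))
  p1 <- point_roi(20, 20); p2 <- point_roi(80, 80)
  prof <- sample_line_profile(img, p1, p2)
  t <- prof$position_um / max(prof$position_um)
  gx <- 20 + t * 60; gy <- 20 + t * 60
  analytic <- exp(-((gx - c0)^2 + (gy - c0)^2) / (2 * s^2))
  # bilinear interpolation error on a smooth Gaussian (sigma 6 px) is tiny
  expect_lt(max(abs(prof$intensity - analytic)), 1e-2)
})

test_that("blur background subtraction removes smooth structure, keeps spots", {
  const <- make_image(matrix(5, 64, 64))
  expect_lt(max(blur_background_subtract(const, 10)$pixels), 1e-8)

  # impulse on zero background survives a wide blur almost untouched
  m <- matrix(0, 128, 128); m[64, 64] <- 1000
  out <- blur_background_subtract(make_image(m), 30)
  expect_gt(out$pixels[64, 64], 0.99 * 1000)

  # low-frequency gradient + spot: gradient crushed, spot preserved
  grad <- matrix(rep(seq(0, 100, length.out = 128), each = 128), 128, 128)
  spot <- matrix(0, 128, 128)
  xs <- matrix(rep(0:127, each = 128), 128, 128)
  ys <- matrix(rep(0:127, times = 128), 128, 128)
  spot <- 500 * exp(-((xs - 64)^2 + (ys - 64)^2) / (2 * 2^2))
  out2 <- blur_background_subtract(make_image(grad + spot), 30)
  interior <- out2$pixels[30:98, 30:98]
  resid <- interior - 500 * exp(-((xs[30:98, 30:98] - 64)^2 +
                                    (ys[30:98, 30:98] - 64)^2) / (2 * 2^2))
  expect_lt(max(abs(resid)), diff(range(grad)) / 10)  # gradient reduced > 10x
  expect_gt(out2$pixels[65, 65], 0.95 * 500)          # spot peak reduced < 5%
})

test_that("TIFF stacks round-trip with sidecar calibration", {
  set.seed(3)
  frames <- lapply(1:5, function(i)
    calibrated_image(matrix(runif(64, 0, 500), 8, 8), 0.1, "GFP", i - 1))
  tl <- time_lapse(frames, 0:4)
  path <- file.path(tempdir(), "stack.tif")
  write_image_stack(tl, path)
  back <- read_image_stack(path)
  expect_length(back, 5)
  expect_equal(back$frames[[1]]$pixel_size, 0.1)
  expect_equal(back$timestamps, 0:4)
  expect_equal(back$frames[[3]]$pixels, frames[[3]]$pixels, tolerance = 1e-4)

  # single page
  p1 <- file.path(tempdir(), "single.tif")
  write_image_stack(frames[[1]], p1)
  expect_length(read_image_stack(p1), 1)

  # explicit calibration overrides the sidecar
  expect_equal(read_image_stack(path, pixel_size_um = 0.5)$frames[[1]]$pixel_size,
               0.5)

  # no sidecar and no explicit calibration is an error, never a default
  bare <- file.path(tempdir(), "bare.tif")
  tiff::writeTIFF(matrix(runif(64), 8, 8), bare)
  expect_error(read_image_stack(bare), "calibration")
  expect_length(read_image_stack(bare, pixel_size_um = 0.2), 1)
})

test_that("micrometre outputs are pixel outputs scaled by pixel size", {
  set.seed(5)
  m <- matrix(runif(41 * 41), 41, 41)
  for (ps in c(0.05, 0.1, 0.25)) {
    img <- make_image(m, pixel_size = ps)
    prof <- sample_line_profile(img, point_roi(2, 3), point_roi(30, 35))
    len_px <- sqrt(28^2 + 32^2)
    expect_equal(max(prof$position_um), len_px * ps)
  }
})
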