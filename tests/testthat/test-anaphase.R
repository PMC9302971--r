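test_that("axis profiles are symmetric two-peak curves on symmetric fixtures", {
  img <- two_mass_image(d_um = 10, sigma_um = 0.8)
  p1 <- point_roi(127.5 - 90, 127.5); p2 <- point_roi(127.5 + 90, 127.5)
  prof <- axis_profile(img, p1, p2)
  expect_equal(attr(prof, "pole_separation_um"), 18)
  m <- split_and_locate_maxima(prof)
  mid <- attr(prof, "pole_separation_um") / 2
  expect_equal(unname(m["pos_right"] - mid), unname(mid - m["pos_left"]),
               tolerance = 1e-6)
  # swapping the poles mirrors the profile but not the separation
  prof_sw <- axis_profile(img, p2, p1)
  expect_equal(mass_separation(prof_sw), mass_separation(prof),
               tolerance = 1e-9)
  # uniform image: flat profile
  flat <- axis_profile(make_image(matrix(4, 64, 64)), point_roi(5, 30),
                       point_roi(55, 30))
  expect_equal(unique(flat$intensity), 4)
})

test_that("half-profile maxima land where they are constructed", {
  # peaks at 25% and 75% of a 20 um axis -> 5 and 15 um
  img <- two_mass_image(d_um = 10, sigma_um = 0.5)  # axis 18 um, peaks at 4/14
  p1 <- point_roi(127.5 - 100, 127.5); p2 <- point_roi(127.5 + 100, 127.5)
  prof <- axis_profile(img, p1, p2)  # 20 um axis, peaks at 5 and 15 um
  m <- split_and_locate_maxima(prof)
  expect_equal(unname(m["pos_left"]), 5, tolerance = 0.1)
  expect_equal(unname(m["pos_right"]), 15, tolerance = 0.1)

  # single central peak: both maxima at/adjacent to the midpoint
  central <- two_mass_image(d_um = 0, sigma_um = 0.8)
  profc <- axis_profile(central, p1, p2)
  expect_lt(mass_separation(profc), 0.2)

  # monotone ramp: left max at its inner boundary, right max at the pole2 end
  ramp <- make_image(matrix(rep(seq(0, 100, length.out = 64), each = 64),
                            64, 64))
  profr <- axis_profile(ramp, point_roi(2, 31), point_roi(60, 31))
  mr <- split_and_locate_maxima(profr)
  psep <- attr(profr, "pole_separation_um")
  expect_lte(abs(mr["pos_left"] - psep / 2), 0.11)
  expect_equal(unname(mr["pos_right"]), psep)
})

test_that("mass separation is invariant to reversal and affine intensity maps", {
  img <- two_mass_image(d_um = 8, sigma_um = 0.6)
  p1 <- point_roi(127.5 - 90, 127.5); p2 <- point_roi(127.5 + 90, 127.5)
  d0 <- mass_separation(axis_profile(img, p1, p2))
  expect_equal(mass_separation(axis_profile(img, p2, p1)), d0,
               tolerance = 1e-9)
  aff <- calibrated_image(img$pixels * 2.5 + 40, img$pixel_size)
  expect_equal(mass_separation(axis_profile(aff, p1, p2)), d0)
  expect_lte(abs(d0 - 8), 2 * img$pixel_size)
})

test_that("separation series recovers generator trajectories frame by frame", {
  recongress <- function(t) if (t <= 3) 2 * t else if (t <= 7) 6 - (t - 3)
    else 2 + (t - 7)
  sp <- anaphase_spec(recongress, mass_sigma = 0.5, n_frames = 11)
  a <- generate_anaphase(sp)
  s <- separation_series(a$chromosomes, a$poles, onset_frame = 1,
                         centromere_movie = a$centromeres)
  ps <- a$chromosomes$frames[[1]]$pixel_size
  expect_true(all(s$status == "ok"))
  expect_true(all(abs(s$mass_separation_um - a$truth$mass_separation_um) <=
                    2 * ps))
  expect_true(all(abs(s$centromere_separation_um -
                        a$truth$centromere_separation_um) <= 2 * ps))
  # pole separation from coordinates is exact
  expect_equal(s$pole_separation_um, a$truth$pole_separation_um)
  # decomposition identity: left + gap + right spans the axis exactly
  expect_equal(s$left_mass_to_pole_um + s$mass_separation_um +
                 s$right_mass_to_pole_um,
               s$pole_separation_um, tolerance = 1e-9)

  # monotone trajectory: measured series is monotone too
  mono <- generate_anaphase(anaphase_spec(function(t) pmin(2.1 * t, 14),
                                          mass_sigma = 0.5, n_frames = 11))
  sm <- separation_series(mono$chromosomes, mono$poles)
  expect_true(all(diff(sm$mass_separation_um) >= -1e-9))
  expect_equal(distance_at(sm, 7), 14, tolerance = 2 * ps)
})

test_that("per-frame failures are flagged and the series continues", {
  a <- generate_anaphase(anaphase_spec(function(t) pmin(2 * t, 10),
                                       mass_sigma = 0.5, n_frames = 5))
  poles <- a$poles[a$poles$frame != 3, ]
  s <- separation_series(a$chromosomes, poles)
  expect_equal(sum(s$status == "ok"), 4)
  expect_true(is.na(s$mass_separation_um[3]))
})

test_that("distance_at uses the nearest acquired sample, earlier on ties", {
  s <- data.frame(time_min = c(0, 2, 4, 6),
                  mass_separation_um = c(0, 3, 6, 9))
  expect_equal(distance_at(s, 4), 6)
  expect_equal(distance_at(s, 3), 3)   # equidistant 2 and 4: earlier wins
  expect_equal(distance_at(s, 5.9), 9)
  expect_error(distance_at(s, -1), "outside")
  expect_error(distance_at(s, 7), "outside")
})

test_that("Gaussian FWHM fits honour the analytic width identity", {
  const <- 2 * sqrt(2 * log(2))
  for (sig in c(0.5, 1, 2)) {
    x <- seq(0, 12, by = 0.05)
    v <- 10 * exp(-(x - 6)^2 / (2 * sig^2)) + 2
    fit <- mass_fwhm(x, v)
    expect_true(fit$fit_ok)
    expect_equal(fit$fwhm_um / fit$fit_sigma_um, const, tolerance = 1e-7)
    expect_equal(fit$fit_sigma_um, sig, tolerance = 1e-6)
    expect_equal(fit$fit_center_um, 6, tolerance = 1e-6)
  }
  # 1% amplitude noise: FWHM within 5% of the analytic value
  set.seed(8)
  x <- seq(0, 16, by = 0.05)
  v <- 10 * exp(-(x - 8)^2 / (2 * 2^2)) + rnorm(length(x), 0, 0.1)
  fit <- mass_fwhm(x, pmax(v, 0))
  expect_true(fit$fit_ok)
  expect_lt(abs(fit$fwhm_um - 4.7096) / 4.7096, 0.05)

  expect_error(mass_fwhm(1:10, rep(5, 10)), "constant")
  expect_error(mass_fwhm(1:3, c(1, 2, 1)), "4 samples")
})
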