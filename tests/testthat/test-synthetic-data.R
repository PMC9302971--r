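test_that("generators are deterministic given the seed", {
  s <- monopolar_spec(ring_radius = 4, noise_sd = 50, seed = 9L)
  expect_identical(generate_monopolar(s)$image$pixels,
                   generate_monopolar(s)$image$pixels)
  s2 <- monopolar_spec(ring_radius = 4, noise_sd = 50, seed = 10L)
  expect_false(identical(generate_monopolar(s)$image$pixels,
                         generate_monopolar(s2)$image$pixels))

  f <- frap_spec(noise_sd = 2, seed = 3L)
  expect_identical(generate_frap_trace(f)$trace$bleached,
                   generate_frap_trace(f)$trace$bleached)

  g <- growth_spec(count_noise_cv = 0.05, seed = 4L)
  expect_identical(generate_growth_curve(g)$curve$count,
                   generate_growth_curve(g)$curve$count)
})

test_that("monopolar ring peaks at the specified radius", {
  g <- generate_monopolar(monopolar_spec(ring_radius = 5, noise_sd = 0))
  prof <- radial_profile(g$image, point_roi(127.5, 127.5))
  expect_lt(abs(distance_to_max(prof) - 5), attr(prof, "bin_width_um"))
  # collapsed-force geometry is generable too
  g2 <- generate_monopolar(monopolar_spec(ring_radius = 1.6, noise_sd = 0))
  prof2 <- radial_profile(g2$image, point_roi(127.5, 127.5))
  expect_lt(abs(distance_to_max(prof2) - 1.6), attr(prof2, "bin_width_um"))
  expect_error(monopolar_spec(ring_radius = 15), "beyond the image")
})

test_that("anaphase truth tables are exact functions of the spec", {
  traj <- function(t) pmin(2.1 * t, 14)
  sp <- anaphase_spec(traj, n_frames = 8, centromere_offset = 1.2)
  a <- generate_anaphase(sp)
  t <- 0:7
  expect_equal(a$truth$mass_separation_um, pmin(2.1 * t, 14))
  expect_equal(a$truth$pole_separation_um, rep(18, 8))
  expect_equal(a$truth$centromere_separation_um, pmin(2.1 * t, 14) + 2.4)
  expect_equal(a$chromosomes$timestamps, t)
  # invariant guards
  expect_error(generate_anaphase(
    anaphase_spec(function(t) 20, pole_trajectory = function(t) 18)),
    "exceed")
  expect_error(anaphase_spec(function(t) -1), "non-negative")
})

test_that("coincident masses give near-zero measured separation", {
  sp <- anaphase_spec(function(t) 0, mass_sigma = 0.5, n_frames = 2)
  a <- generate_anaphase(sp)
  s <- separation_series(a$chromosomes, a$poles)
  expect_lt(max(s$mass_separation_um), 2 * 0.1)
})

test_that("nucleus truth solidity behaves like the continuous polygon", {
  # convex ellipse
  el <- generate_nucleus_mask(nucleus_spec(n_lobes = 0))
  expect_equal(el$truth_solidity, 1, tolerance = 1e-6)
  # lobed: truth below the abnormality range boundary, matches the oracle
  nm <- generate_nucleus_mask(nucleus_spec(n_lobes = 4, lobe_depth = 0.4))
  expect_lt(nm$truth_solidity, 0.939)
  expect_equal(nm$truth_solidity, oracle_polygon_solidity(nm$polygon),
               tolerance = 1e-12)
  # truth_solidity increases monotonically to 1 as lobe depth vanishes
  depths <- c(0.4, 0.2, 0.1, 0.05, 0)
  truths <- vapply(depths, function(d)
    generate_nucleus_mask(nucleus_spec(n_lobes = 4, lobe_depth = d))$truth_solidity,
    numeric(1))
  expect_true(all(diff(truths) > 0 | (depths[-1] == 0 & truths[-1] == 1)))
  expect_equal(truths[length(truths)], 1, tolerance = 1e-6)
})

test_that("rasterized solidity converges to the polygon truth with resolution", {
  sp_coarse <- nucleus_spec(n_lobes = 4, lobe_depth = 0.4, pixel_size = 0.15)
  sp_fine <- nucleus_spec(n_lobes = 4, lobe_depth = 0.4, pixel_size = 0.05)
  coarse <- generate_nucleus_mask(sp_coarse)
  fine <- generate_nucleus_mask(sp_fine)
  err_coarse <- abs(solidity(coarse$mask) - coarse$truth_solidity)
  err_fine <- abs(solidity(fine$mask) - fine$truth_solidity)
  expect_lt(err_fine, err_coarse)
  # at the default working resolution the residual is small
  default <- generate_nucleus_mask(nucleus_spec(n_lobes = 4, lobe_depth = 0.4))
  expect_lt(abs(solidity(default$mask) - default$truth_solidity), 0.02)
})

test_that("FRAP generator reproduces its sampling schedule and regimes", {
  g <- generate_frap_trace(frap_spec(bleach_depth = 0.18, mobile_fraction = 0))
  tr <- g$trace
  expect_equal(tr$times[1:6], seq(-25, 0, by = 5))
  expect_equal(tr$times[7:36], seq(20, 600, by = 20))
  expect_equal(tr$bleach_index, 7L)
  nt <- normalize_trace(tr)
  # immobile pool: flat at the bleach depth after the bleach
  expect_equal(nt$normalized[7:36], rep(0.18, 30), tolerance = 1e-12)

  # fully mobile, fast recovery: interphase-like complete recovery at 220 s
  g2 <- generate_frap_trace(frap_spec(bleach_depth = 0.3, mobile_fraction = 1,
                                      recovery_tau = 20))
  expect_gt(recovery_at(normalize_trace(g2$trace), 220), 95)

  # metaphase-like regime: deep bleach, small mobile fraction
  g3 <- generate_frap_trace(frap_spec(bleach_depth = 0.18,
                                      mobile_fraction = 0.09,
                                      recovery_tau = 60))
  nt3 <- normalize_trace(g3$trace)
  expect_equal(postbleach_fraction(nt3), 18, tolerance = 1e-9)
  expect_lt(abs(recovery_at(nt3, 220) - 25), 1)
})

test_that("growth generator matches the exponential closed form", {
  g <- generate_growth_curve(growth_spec(b = 2, tau = 20.72))
  curve <- normalize_curve(g$curve)
  expect_equal(round(fold_change(curve, 48), 2), 4.98)
  expect_equal(fold_change(curve, 0), 1)
  g2 <- generate_growth_curve(growth_spec(b = 1.4, tau = 20.72))
  expect_equal(round(fold_change(normalize_curve(g2$curve), 48), 2), 2.18)
})
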