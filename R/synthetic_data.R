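#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

gaussian_spot <- function(nx, ny, cx, cy, sigma_px, peak) {
  x <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)
  y <- matrix(rep(0:(ny - 1L), times = nx), ny, nx)
  peak * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma_px^2))
}

#' Synthetic monopolar-spindle image
#'
#' Emulates a monopolar mitotic cell in which polar ejection forces push
#' chromatin radially away from a single spindle pole: DAPI-like intensity is
#' a Gaussian ring `I(r) = peak * exp(-(r - ring_radius)^2 / (2 ring_width^2))`
#' around the pole, plus optional additive Gaussian noise (clipped at zero).
#' The ring radius is the ground truth recovered by the polar-ejection-force
#' assay.
#'
#' @param image_size Image side length in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param pole Pole position as a [point_roi()]; defaults to the image center.
#' @param ring_radius True pole-to-chromatin distance (um).
#' @param ring_width Radial Gaussian standard deviation of the ring (um).
#' @param peak_intensity Ring peak intensity (a.u.).
#' @param noise_sd Additive Gaussian noise standard deviation (a.u.).
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return A `monopolar_spec` (for `monopolar_spec()`), or a list with
#'   elements `image` (a [calibrated_image()]) and `truth`
#'   (`list(ring_radius)`) for [generate_monopolar()].
#' @export
monopolar_spec <- function(image_size = 256L, pixel_size = 0.1, pole = NULL,
                           ring_radius = 3.7, ring_width = 0.4,
                           peak_intensity = 1000, noise_sd = 0, seed = 1L) {
  if (is.null(pole))
    pole <- point_roi((image_size - 1) / 2, (image_size - 1) / 2)
  stopifnot(inherits(pole, "point_roi"), ring_radius > 0, ring_width > 0,
            peak_intensity > 0, noise_sd >= 0)
  half_extent <- min(pole$x, pole$y, image_size - 1 - pole$x,
                     image_size - 1 - pole$y) * pixel_size
  if (ring_radius + 3 * ring_width > half_extent)
    stop("ring extends beyond the image; enlarge `image_size`")
  structure(list(image_size = as.integer(image_size), pixel_size = pixel_size,
                 pole = pole, ring_radius = ring_radius,
                 ring_width = ring_width, peak_intensity = peak_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "monopolar_spec")
}

#' @param spec A [monopolar_spec()].
#' @rdname monopolar_spec
#' @export
generate_monopolar <- function(spec) {
  stopifnot(inherits(spec, "monopolar_spec"))
  n <- spec$image_size
  x <- matrix(rep(0:(n - 1L), each = n), n, n)
  y <- matrix(rep(0:(n - 1L), times = n), n, n)
  r_um <- sqrt((x - spec$pole$x)^2 + (y - spec$pole$y)^2) * spec$pixel_size
  img <- spec$peak_intensity *
    exp(-(r_um - spec$ring_radius)^2 / (2 * spec$ring_width^2))
  if (spec$noise_sd > 0)
    img <- with_seed(spec$seed,
                     img + stats::rnorm(length(img), 0, spec$noise_sd))
  img <- pmax(img, 0)
  list(image = calibrated_image(img, spec$pixel_size, "DAPI"),
       truth = list(ring_radius = spec$ring_radius))
}

#' Synthetic anaphase time-lapse
#'
#' Emulates a bipolar anaphase cell imaged at fixed intervals: two isotropic
#' Gaussian chromosome masses centered symmetrically about the spindle
#' midpoint along the pole-to-pole axis, their separation following a
#' prescribed trajectory `d(t)` (monotone segregation, or rise–dip–rise
#' recongression), plus a spindle-pole marker channel and a centromere marker
#' channel whose peaks sit at each mass center displaced toward its pole.
#' The returned truth table is an exact function of the spec.
#'
#' @param separation_trajectory Function `t_min -> d` (um between mass
#'   centers, >= 0).
#' @param mass_sigma Gaussian chromosome-mass standard deviation (um).
#' @param pole_trajectory Function `t_min -> pole separation` (um); must
#'   exceed `d(t)` at every frame (poles outside the masses).
#' @param centromere_offset Centromere peak displacement from the mass center
#'   toward its pole (um).
#' @param frame_interval Time between frames (min).
#' @param n_frames Number of frames; frame 1 is anaphase onset (t = 0).
#' @param image_size,pixel_size Field geometry as in [monopolar_spec()].
#' @param peak_intensity Peak intensity of each Gaussian component (a.u.).
#' @param noise_sd Additive Gaussian noise sd (a.u.), clipped at zero.
#' @param seed RNG seed.
#' @return For [generate_anaphase()], a list with `chromosomes`, `poles_ch`,
#'   `centromeres` (each a [time_lapse()]), `poles` (data frame of pole
#'   marker coordinates per frame, in pixels), and `truth` (data frame with
#'   per-frame `time_min`, `mass_separation_um`, `pole_separation_um`,
#'   `centromere_separation_um`, and marker coordinates).
#' @export
anaphase_spec <- function(separation_trajectory,
                          mass_sigma = 1.5,
                          pole_trajectory = function(t) 18,
                          centromere_offset = 1,
                          frame_interval = 1, n_frames = 11L,
                          image_size = 256L, pixel_size = 0.1,
                          peak_intensity = 1000, noise_sd = 0, seed = 1L) {
  stopifnot(is.function(separation_trajectory), is.function(pole_trajectory),
            mass_sigma > 0, centromere_offset >= 0, frame_interval > 0,
            n_frames >= 1, noise_sd >= 0)
  t <- (seq_len(n_frames) - 1) * frame_interval
  d <- vapply(t, separation_trajectory, numeric(1))
  psep <- vapply(t, pole_trajectory, numeric(1))
  if (any(d < 0)) stop("separation trajectory must be non-negative")
  if (any(psep <= d))
    stop("pole separation must exceed mass separation at every frame")
  half_extent <- (image_size - 1) / 2 * pixel_size
  if (any(psep / 2 + 0.5 > half_extent) ||
      any(d / 2 + centromere_offset + 3 * mass_sigma > half_extent))
    stop("spindle leaves the field of view; enlarge `image_size`")
  structure(list(separation_trajectory = separation_trajectory,
                 mass_sigma = mass_sigma, pole_trajectory = pole_trajectory,
                 centromere_offset = centromere_offset,
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 image_size = as.integer(image_size),
                 pixel_size = pixel_size, peak_intensity = peak_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "anaphase_spec")
}

#' @param spec An [anaphase_spec()].
#' @rdname anaphase_spec
#' @export
generate_anaphase <- function(spec) {
  stopifnot(inherits(spec, "anaphase_spec"))
  n <- spec$image_size; ps <- spec$pixel_size
  c0 <- (n - 1) / 2
  t <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  d <- vapply(t, spec$separation_trajectory, numeric(1))
  psep <- vapply(t, spec$pole_trajectory, numeric(1))
  truth <- data.frame(
    frame = seq_len(spec$n_frames), time_min = t,
    mass_separation_um = d, pole_separation_um = psep,
    centromere_separation_um = d + 2 * spec$centromere_offset,
    mass_left_x = c0 - d / (2 * ps), mass_right_x = c0 + d / (2 * ps),
    cen_left_x = c0 - (d / 2 + spec$centromere_offset) / ps,
    cen_right_x = c0 + (d / 2 + spec$centromere_offset) / ps,
    pole1_x = c0 - psep / (2 * ps), pole2_x = c0 + psep / (2 * ps),
    axis_y = c0)
  add_noise <- function(img, sub_seed) {
    if (spec$noise_sd == 0) return(pmax(img, 0))
    with_seed(sub_seed,
              pmax(img + stats::rnorm(length(img), 0, spec$noise_sd), 0))
  }
  mk_frames <- function(centers_x, sigma_px, seed_offset, channel) {
    frames <- lapply(seq_len(spec$n_frames), function(i) {
      img <- Reduce(`+`, lapply(centers_x[[i]], function(cx)
        gaussian_spot(n, n, cx, c0, sigma_px, spec$peak_intensity)))
      img <- add_noise(img, spec$seed + seed_offset * 1000L + i)
      calibrated_image(img, ps, channel, t[i])
    })
    time_lapse(frames, t)
  }
  sig_mass <- spec$mass_sigma / ps
  chrom <- mk_frames(lapply(seq_len(spec$n_frames), function(i)
    c(truth$mass_left_x[i], truth$mass_right_x[i])), sig_mass, 0L, "chromosomes")
  poles_ch <- mk_frames(lapply(seq_len(spec$n_frames), function(i)
    c(truth$pole1_x[i], truth$pole2_x[i])), 2, 1L, "poles")
  cen <- mk_frames(lapply(seq_len(spec$n_frames), function(i)
    c(truth$cen_left_x[i], truth$cen_right_x[i])), 3, 2L, "centromeres")
  poles <- data.frame(frame = truth$frame,
                      pole1_x = truth$pole1_x, pole1_y = truth$axis_y,
                      pole2_x = truth$pole2_x, pole2_y = truth$axis_y)
  list(chromosomes = chrom, poles_ch = poles_ch, centromeres = cen,
       poles = poles, truth = truth)
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Synthetic lobed-nucleus mask with known solidity
#'
#' Emulates interphase nuclei ranging from smooth ovals to lobed, abnormally
#' shaped nuclei. The boundary is a cosine-modulated ellipse,
#' `r(theta) = r_ellipse(theta) * (1 - lobe_depth * max(0, cos(n_lobes * theta
#' + phase)))`, rasterized by the pixel-center rule. The ground-truth solidity
#' is computed from the continuous polygon (shoelace area over convex-hull
#' area of dense boundary samples), independent of rasterization.
#'
#' @param base_axes Ellipse semi-axes `c(a, b)` in um.
#' @param n_lobes Number of lobes (integer >= 0; 0 gives a plain ellipse).
#' @param lobe_depth Lobe indentation as a fraction of the local radius, in
#'   `[0, 1)`.
#' @param phase Angular phase of the lobe pattern (radians).
#' @param pixel_size Rasterization pixel size (um/px).
#' @param n_boundary Number of dense boundary samples for the truth polygon.
#' @param seed RNG seed (kept for interface symmetry; generation is
#'   deterministic).
#' @return For [generate_nucleus_mask()], a list with `mask` (logical
#'   matrix), `truth_solidity`, `polygon` (two-column matrix, um), and
#'   `pixel_size`.
#' @export
nucleus_spec <- function(base_axes = c(5, 3.5), n_lobes = 0L, lobe_depth = 0,
                         phase = 0, pixel_size = 0.1, n_boundary = 2048L,
                         seed = 1L) {
  stopifnot(length(base_axes) == 2, all(base_axes > 0),
            n_lobes >= 0, lobe_depth >= 0, lobe_depth < 1, pixel_size > 0)
  structure(list(base_axes = base_axes, n_lobes = as.integer(n_lobes),
                 lobe_depth = lobe_depth, phase = phase,
                 pixel_size = pixel_size, n_boundary = as.integer(n_boundary),
                 seed = as.integer(seed)),
            class = "nucleus_spec")
}

nucleus_polygon <- function(spec) {
  a <- spec$base_axes[1]; b <- spec$base_axes[2]
  th <- seq(0, 2 * pi, length.out = spec$n_boundary + 1L)[-(spec$n_boundary + 1L)]
  re <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  mod <- 1 - spec$lobe_depth * pmax(0, cos(spec$n_lobes * th + spec$phase))
  r <- re * mod
  cbind(x = r * cos(th), y = r * sin(th))
}

#' @param spec A [nucleus_spec()].
#' @rdname nucleus_spec
#' @export
generate_nucleus_mask <- function(spec) {
  stopifnot(inherits(spec, "nucleus_spec"))
  poly <- nucleus_polygon(spec)
  area <- shoelace_area(poly[, 1], poly[, 2])
  if (area <= 0) stop("degenerate nucleus polygon")
  hull <- poly[grDevices::chull(poly), , drop = FALSE]
  hull_area <- shoelace_area(hull[, 1], hull[, 2])
  truth <- area / hull_area
  ext <- max(abs(poly)) + 2 * spec$pixel_size
  half_n <- ceiling(ext / spec$pixel_size)
  coords <- (-half_n:half_n) * spec$pixel_size
  g <- cbind(x = rep(coords, times = length(coords)),
             y = rep(coords, each = length(coords)))
  closed <- rbind(poly, poly[1, ])
  inside <- mgcv::in.out(closed, g)
  mask <- matrix(FALSE, length(coords), length(coords))  # rows = y, cols = x
  mask[cbind(match(g[inside, "y"], coords), match(g[inside, "x"], coords))] <- TRUE
  list(mask = mask, truth_solidity = truth, polygon = poly,
       pixel_size = spec$pixel_size)
}

#' Synthetic FRAP trace
#'
#' Emulates the photobleaching acquisition schedule — frames every 5 s for
#' 25 s before the bleach (the last pre-bleach frame at t = 0), then every
#' 20 s for 10 min after — with a single-exponential mobile/immobile recovery
#' model. The bleached-ROI signal at post-bleach time t is
#' `B + P * (d + m * (1 - d) * (1 - exp(-(t - t1)/tau_rec)))` with prebleach
#' level `P`, background `B`, bleach depth `d` (fraction remaining), mobile
#' fraction `m`, and `t1` the first post-bleach frame, so the first
#' post-bleach sample equals `d` exactly after normalization. The unbleached
#' ROI stays at `P + B`.
#'
#' @param prebleach_level Pre-bleach background-free signal `P` (a.u.).
#' @param bleach_depth Fraction of signal remaining immediately post-bleach.
#' @param mobile_fraction Fraction of the bleached pool that exchanges.
#' @param recovery_tau Recovery time constant (s).
#' @param background_level Constant background `B` (a.u.).
#' @param noise_sd Additive Gaussian noise sd applied per sample (a.u.).
#' @param seed RNG seed.
#' @return For [generate_frap_trace()], a list with `trace` (a
#'   [frap_trace()]) and `truth` (`bleach_depth`, `mobile_fraction`,
#'   `plateau`, `recovery_tau`).
#' @export
frap_spec <- function(prebleach_level = 100, bleach_depth = 0.2,
                      mobile_fraction = 1, recovery_tau = 60,
                      background_level = 10, noise_sd = 0, seed = 1L) {
  stopifnot(prebleach_level > 0, bleach_depth >= 0, bleach_depth <= 1,
            mobile_fraction >= 0, mobile_fraction <= 1, recovery_tau > 0,
            background_level >= 0, noise_sd >= 0)
  structure(list(prebleach_level = prebleach_level,
                 bleach_depth = bleach_depth,
                 mobile_fraction = mobile_fraction,
                 recovery_tau = recovery_tau,
                 background_level = background_level,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "frap_spec")
}

#' @param spec A [frap_spec()].
#' @rdname frap_spec
#' @export
generate_frap_trace <- function(spec) {
  stopifnot(inherits(spec, "frap_spec"))
  t_pre <- seq(-25, 0, by = 5)
  t_post <- seq(20, 600, by = 20)
  times <- c(t_pre, t_post)
  P <- spec$prebleach_level; B <- spec$background_level
  d <- spec$bleach_depth; m <- spec$mobile_fraction
  rec <- d + m * (1 - d) * (1 - exp(-(t_post - t_post[1]) / spec$recovery_tau))
  bleached <- c(rep(P + B, length(t_pre)), B + P * rec)
  unbleached <- rep(P + B, length(times))
  background <- rep(B, length(times))
  if (spec$noise_sd > 0) {
    noisy <- with_seed(spec$seed, {
      list(b = bleached + stats::rnorm(length(times), 0, spec$noise_sd),
           u = unbleached + stats::rnorm(length(times), 0, spec$noise_sd),
           g = background + stats::rnorm(length(times), 0, spec$noise_sd))
    })
    bleached <- pmax(noisy$b, 0); unbleached <- pmax(noisy$u, 0)
    background <- pmax(noisy$g, 0)
  }
  trace <- frap_trace(times, bleached, unbleached, background,
                      bleach_index = length(t_pre) + 1L)
  list(trace = trace,
       truth = list(bleach_depth = d, mobile_fraction = m,
                    plateau = d + m * (1 - d),
                    recovery_tau = spec$recovery_tau))
}

#' Synthetic proliferation curve
#'
#' Emulates automated-imaging cell counts collected at fixed intervals:
#' `N(t) = initial_count * b^(t / tau) * (1 + eps_t)` with i.i.d. mean-zero
#' multiplicative noise of coefficient of variation `count_noise_cv`. The
#' per-cycle multiplication factor `b` is 2 when every cell divides and
#' `2 - f` when a fraction `f` fails to divide each cycle.
#'
#' @param b Per-cycle multiplication factor (> 1).
#' @param tau Doubling period (hr).
#' @param t_max Assay duration (hr).
#' @param sample_interval Imaging interval (hr).
#' @param initial_count Cells per well at time 0.
#' @param count_noise_cv Coefficient of variation of the multiplicative count
#'   noise.
#' @param well_id,condition Labels carried into the output curve.
#' @param seed RNG seed.
#' @return For [generate_growth_curve()], a list with `curve` (data frame
#'   `well_id`, `condition`, `time_hr`, `count`) and `truth` (`b`, `tau`).
#' @export
growth_spec <- function(b = 2, tau = 20.72, t_max = 96, sample_interval = 4,
                        initial_count = 12000, count_noise_cv = 0,
                        well_id = "W1", condition = "control", seed = 1L) {
  stopifnot(b > 1, tau > 0, t_max > 0, sample_interval > 0,
            initial_count > 0, count_noise_cv >= 0)
  structure(list(b = b, tau = tau, t_max = t_max,
                 sample_interval = sample_interval,
                 initial_count = initial_count,
                 count_noise_cv = count_noise_cv,
                 well_id = well_id, condition = condition,
                 seed = as.integer(seed)),
            class = "growth_spec")
}

#' @param spec A [growth_spec()].
#' @rdname growth_spec
#' @export
generate_growth_curve <- function(spec) {
  stopifnot(inherits(spec, "growth_spec"))
  t <- seq(0, spec$t_max, by = spec$sample_interval)
  counts <- spec$initial_count * spec$b^(t / spec$tau)
  if (spec$count_noise_cv > 0)
    counts <- with_seed(spec$seed,
      counts * pmax(1 + stats::rnorm(length(t), 0, spec$count_noise_cv), 0.01))
  curve <- data.frame(well_id = spec$well_id, condition = spec$condition,
                      time_hr = t, count = counts)
  list(curve = curve, truth = list(b = spec$b, tau = spec$tau))
}
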