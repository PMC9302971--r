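#' Intensity profile along the pole-to-pole axis
#'
#' Samples the image along the line through both spindle poles (the
#' pole-to-pole segment) via [sample_line_profile()]; positions run from 0 at
#' `pole1` to the pole separation at `pole2`, in micrometres. This is the
#' substrate of all anaphase separation measurements.
#'
#' @param frame A [calibrated_image()].
#' @param pole1,pole2 Distinct [point_roi()] spindle-pole positions.
#' @param spacing_px Sample spacing (px), default 1.
#' @return A data frame of class `axis_profile` (columns `position_um`,
#'   `intensity`) with attribute `pole_separation_um`.
#' @export
axis_profile <- function(frame, pole1, pole2, spacing_px = 1) {
  prof <- sample_line_profile(frame, pole1, pole2, spacing_px)
  class(prof) <- c("axis_profile", class(prof))
  attr(prof, "pole_separation_um") <-
    sqrt((pole2$x - pole1$x)^2 + (pole2$y - pole1$y)^2) * frame$pixel_size
  prof
}

#' Split an axis profile at the spindle midpoint and locate the two maxima
#'
#' The profile is split at half the pole separation into two half-spindle
#' profiles, each containing one segregating chromosome mass; within each
#' half the position of the global intensity maximum is returned. Ties are
#' broken toward the midpoint. An optional 3-sample moving average can smooth
#' before max-finding (default off: raw maxima).
#'
#' @param profile An [axis_profile()].
#' @param smooth_window Odd moving-average width; 1 disables smoothing.
#' @return Named numeric vector `c(pos_left, pos_right)` in um from pole1.
#' @export
split_and_locate_maxima <- function(profile, smooth_window = 1L) {
  stopifnot(inherits(profile, "axis_profile"))
  mid <- attr(profile, "pole_separation_um") / 2
  v <- profile$intensity
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) stop("`smooth_window` must be odd")
    sm <- stats::filter(v, rep(1 / smooth_window, smooth_window), sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))
  }
  left <- which(profile$position_um <= mid)
  right <- which(profile$position_um >= mid)
  if (length(left) < 2L || length(right) < 2L)
    stop("each half-profile needs at least 2 samples")
  vl <- v[left]; vr <- v[right]
  # ties toward the midpoint: last max in the left half, first in the right
  il <- left[max(which(vl == max(vl)))]
  ir <- right[min(which(vr == max(vr)))]
  c(pos_left = profile$position_um[il], pos_right = profile$position_um[ir])
}

#' Distance between segregating chromosome masses
#'
#' The separation between the two half-spindle intensity maxima of an axis
#' profile, in micrometres. Non-negative by construction; invariant under
#' axis reversal and under positive affine transforms of intensity.
#'
#' @inheritParams split_and_locate_maxima
#' @return Mass separation (um).
#' @export
mass_separation <- function(profile, smooth_window = 1L) {
  m <- split_and_locate_maxima(profile, smooth_window)
  unname(m["pos_right"] - m["pos_left"])
}

#' Per-frame anaphase separation series
#'
#' Measures chromosome-mass separation over an anaphase time-lapse, with
#' times reported in minutes after anaphase onset. Optionally decomposes each
#' frame further: pole separation (Euclidean distance between the supplied
#' pole coordinates), centromere separation (the centromere channel profiled
#' along the same axis), and per-half-spindle mass-to-pole and
#' centromere-to-pole distances — the anaphase A/B decomposition. Per-frame
#' failures are flagged in `status` and the series continues.
#'
#' @param movie A [time_lapse()] of the chromosome channel; timestamps in
#'   minutes.
#' @param poles Data frame with one row per frame: columns `frame`,
#'   `pole1_x`, `pole1_y`, `pole2_x`, `pole2_y` (0-based pixel coordinates).
#' @param onset_frame Frame index (1-based) of anaphase onset; defines t = 0.
#' @param centromere_movie Optional [time_lapse()] of the centromere channel,
#'   frame-aligned with `movie`.
#' @param background_subtract If `TRUE`, apply [blur_background_subtract()]
#'   with `blur_sigma_px` to marker channels before profiling.
#' @param blur_sigma_px Blur sigma for the background subtraction (px).
#' @param smooth_window Passed to [split_and_locate_maxima()].
#' @return A data frame of class `separation_series`: `frame`, `time_min`,
#'   `mass_separation_um`, `pole_separation_um`, `centromere_separation_um`,
#'   `left_mass_to_pole_um`, `right_mass_to_pole_um`,
#'   `left_cen_to_pole_um`, `right_cen_to_pole_um`, `status`.
#' @export
separation_series <- function(movie, poles, onset_frame = 1L,
                              centromere_movie = NULL,
                              background_subtract = FALSE,
                              blur_sigma_px = 30, smooth_window = 1L) {
  stopifnot(inherits(movie, "time_lapse"))
  n <- length(movie)
  need <- c("frame", "pole1_x", "pole1_y", "pole2_x", "pole2_y")
  if (!all(need %in% names(poles)))
    stop("`poles` must have columns ", paste(need, collapse = ", "))
  if (onset_frame < 1L || onset_frame > n)
    stop("`onset_frame` outside the movie")
  if (!is.null(centromere_movie) && length(centromere_movie) != n)
    stop("centromere movie must be frame-aligned with the chromosome movie")
  t0 <- movie$timestamps[onset_frame]
  rows <- lapply(seq_len(n), function(i) {
    p <- poles[poles$frame == i, , drop = FALSE]
    out <- data.frame(frame = i, time_min = movie$timestamps[i] - t0,
                      mass_separation_um = NA_real_,
                      pole_separation_um = NA_real_,
                      centromere_separation_um = NA_real_,
                      left_mass_to_pole_um = NA_real_,
                      right_mass_to_pole_um = NA_real_,
                      left_cen_to_pole_um = NA_real_,
                      right_cen_to_pole_um = NA_real_,
                      status = "ok")
    tryCatch({
      if (nrow(p) != 1L) stop("no pole coordinates for frame ", i)
      p1 <- point_roi(p$pole1_x, p$pole1_y)
      p2 <- point_roi(p$pole2_x, p$pole2_y)
      frame <- movie$frames[[i]]
      if (background_subtract)
        frame <- blur_background_subtract(frame, blur_sigma_px)
      prof <- axis_profile(frame, p1, p2)
      psep <- attr(prof, "pole_separation_um")
      m <- split_and_locate_maxima(prof, smooth_window)
      out$mass_separation_um <- unname(m["pos_right"] - m["pos_left"])
      out$pole_separation_um <- psep
      out$left_mass_to_pole_um <- unname(m["pos_left"])
      out$right_mass_to_pole_um <- unname(psep - m["pos_right"])
      if (!is.null(centromere_movie)) {
        cframe <- centromere_movie$frames[[i]]
        if (background_subtract)
          cframe <- blur_background_subtract(cframe, blur_sigma_px)
        cprof <- axis_profile(cframe, p1, p2)
        cm <- split_and_locate_maxima(cprof, smooth_window)
        out$centromere_separation_um <- unname(cm["pos_right"] - cm["pos_left"])
        out$left_cen_to_pole_um <- unname(cm["pos_left"])
        out$right_cen_to_pole_um <- unname(psep - cm["pos_right"])
      }
      out
    }, error = function(e) {
      out$status <- conditionMessage(e)
      out
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("separation_series", "data.frame")
  out
}

#' Series value at a fixed time after anaphase onset
#'
#' Returns the series value at the sampled frame nearest `t` minutes after
#' onset (the assay reports distances at acquired timepoints, e.g. 7 or
#' 10 min; no interpolation). When two frames are equidistant from `t`, the
#' earlier one is used. `t` outside the sampled range is an error.
#'
#' @param series A [separation_series()] (or any data frame with `time_min`).
#' @param t Time after anaphase onset (min).
#' @param what Column to read, default `"mass_separation_um"`.
#' @return The series value at the nearest sample (um).
#' @export
distance_at <- function(series, t, what = "mass_separation_um") {
  if (!what %in% names(series)) stop("no column `", what, "` in series")
  tm <- series$time_min
  if (!length(tm)) stop("empty series")
  if (t < min(tm) || t > max(tm))
    stop("t = ", t, " min outside the sampled range [", min(tm), ", ",
         max(tm), "]")
  dt <- abs(tm - t)
  i <- which(dt == min(dt))[1]  # earlier sample on ties (times increasing)
  series[[what]][i]
}

#' Gaussian full width at half maximum of a chromosome-mass profile
#'
#' Fits `A * exp(-(x - mu)^2 / (2 sigma^2)) + c` to a half-spindle intensity
#' profile by nonlinear least squares and reports the full width at half
#' maximum `2 * sqrt(2 ln 2) * sigma` — the broadness measure for segregating
#' chromosome masses. Initialization: `mu` at the argmax, `sigma` from the
#' second moment about it, `A` peak-minus-baseline, `c` the profile minimum.
#' `fit_ok` is `FALSE` when the fit does not converge or the fitted sigma
#' exceeds half the profile length (the profile is not a resolvable peak).
#'
#' @param positions_um Sample positions (um), strictly increasing, length
#'   >= 4.
#' @param intensities Intensities (a.u.); must not be constant.
#' @return A list of class `mass_width`: `fwhm_um`, `fit_center_um`,
#'   `fit_sigma_um`, `fit_offset`, `fit_ok`.
#' @export
mass_fwhm <- function(positions_um, intensities) {
  if (inherits(positions_um, "data.frame")) {
    intensities <- positions_um$intensity
    positions_um <- positions_um$position_um
  }
  if (length(positions_um) < 4L) stop("need at least 4 samples to fit")
  if (max(intensities) == min(intensities))
    stop("constant profile: no peak to fit")
  x <- as.numeric(positions_um); v <- as.numeric(intensities)
  i0 <- which.max(v)
  w <- pmax(v - min(v), 0)
  sigma0 <- sqrt(sum(w * (x - x[i0])^2) / sum(w))
  if (!is.finite(sigma0) || sigma0 <= 0) sigma0 <- diff(range(x)) / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ A * exp(-(x - mu)^2 / (2 * sigma^2)) + c0,
      start = list(A = max(v) - min(v), mu = x[i0], sigma = sigma0,
                   c0 = min(v)),
      lower = c(A = 0, mu = min(x), sigma = 1e-6, c0 = -Inf),
      upper = c(A = Inf, mu = max(x), sigma = Inf, c0 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(fwhm_um = NA_real_, fit_center_um = NA_real_,
                fit_sigma_um = NA_real_, fit_offset = NA_real_,
                fit_ok = FALSE)
  } else {
    cf <- stats::coef(fit)
    sigma <- unname(cf["sigma"])
    ok <- isTRUE(fit$convInfo$isConv) && sigma <= diff(range(x)) / 2
    out <- list(fwhm_um = 2 * sqrt(2 * log(2)) * sigma,
                fit_center_um = unname(cf["mu"]),
                fit_sigma_um = sigma,
                fit_offset = unname(cf["c0"]),
                fit_ok = ok)
  }
  class(out) <- "mass_width"
  out
}
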