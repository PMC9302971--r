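#' Normalize a growth curve to its first time point
#'
#' Divides every cell count by the count of the first image acquired at time
#' 0, so the curve starts at 1.
#'
#' @param curve Data frame with columns `time_hr` (strictly increasing,
#'   first sample at 0) and `count`.
#' @return The curve with an added `normalized` column.
#' @export
normalize_curve <- function(curve) {
  check_growth_curve(curve)
  if (curve$count[1] <= 0) stop("first-frame count must be positive")
  curve$normalized <- curve$count / curve$count[1]
  curve
}

check_growth_curve <- function(curve) {
  if (!all(c("time_hr", "count") %in% names(curve)))
    stop("growth curve needs `time_hr` and `count` columns")
  if (!nrow(curve)) stop("empty growth curve")
  if (curve$time_hr[1] != 0) stop("growth curve must start at time 0")
  if (any(diff(curve$time_hr) <= 0))
    stop("`time_hr` must be strictly increasing")
  if (any(curve$count < 0)) stop("counts must be non-negative")
  invisible(curve)
}

#' Filter wells by first-frame cell count
#'
#' Keeps only wells whose count at time 0 lies within the density window
#' (inclusive bounds), the seeding-density control of the proliferation
#' assay. Retained curves are returned unchanged.
#'
#' @param curves Data frame with columns `well_id`, `time_hr`, `count` (long
#'   format, several wells).
#' @param min_first_count,max_first_count Window bounds; defaults 10000 and
#'   20000.
#' @return The subset of `curves` from wells passing the filter.
#' @export
filter_wells <- function(curves, min_first_count = 10000,
                         max_first_count = 20000) {
  if (min_first_count >= max_first_count) stop("filter bounds out of order")
  if (!nrow(curves)) return(curves)
  if (!all(c("well_id", "time_hr", "count") %in% names(curves)))
    stop("`curves` needs `well_id`, `time_hr`, `count` columns")
  keep <- vapply(split(curves, curves$well_id), function(d) {
    first <- d$count[which.min(d$time_hr)]
    first >= min_first_count && first <= max_first_count
  }, logical(1))
  out <- curves[curves$well_id %in% names(keep)[keep], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fold change at a fixed assay time
#'
#' The normalized cell count at time `t` (count at `t` divided by the count
#' at time 0), read at the exact sampling point; `t` absent from the grid is
#' an error.
#'
#' @param curve A [normalize_curve()] result.
#' @param t Assay time (hr), default 96.
#' @return Fold change (dimensionless).
#' @export
fold_change <- function(curve, t = 96) {
  if (!"normalized" %in% names(curve))
    stop("`curve` must be normalized first (see normalize_curve)")
  i <- which(curve$time_hr == t)
  if (!length(i)) stop("t = ", t, " hr is not on the sampling grid")
  curve$normalized[i]
}

#' Doubling time by log-linear regression
#'
#' Ordinary least squares of `log2(normalized count)` on time over an early
#' window (default the first 48 h, before growth plateaus); the doubling
#' time is the reciprocal of the slope. Exactly unbiased on noiseless
#' exponential data. A non-positive slope is flagged as non-growing. An
#' endpoint-ratio alternative (`method = "endpoint"`) estimates
#' `tau = (t2 - t1) / log2(N2/N1)` from the window's first and last samples.
#'
#' @param curve A [normalize_curve()] result.
#' @param window Two-element time window (hr), default `c(0, 48)`.
#' @param method `"ols"` (default) or `"endpoint"`.
#' @return A list of class `doubling_fit`: `tau_hr`, `slope`, `n`,
#'   `growing`.
#' @export
estimate_doubling_time <- function(curve, window = c(0, 48),
                                   method = c("ols", "endpoint")) {
  method <- match.arg(method)
  if (!"normalized" %in% names(curve))
    stop("`curve` must be normalized first (see normalize_curve)")
  sel <- curve$time_hr >= window[1] & curve$time_hr <= window[2] &
    curve$normalized > 0
  d <- curve[sel, , drop = FALSE]
  if (nrow(d) < 3L) stop("need at least 3 positive samples in the window")
  if (method == "ols") {
    fit <- stats::lm(log2(normalized) ~ time_hr, data = d)
    slope <- unname(stats::coef(fit)[2])
  } else {
    n <- nrow(d)
    slope <- log2(d$normalized[n] / d$normalized[1]) /
      (d$time_hr[n] - d$time_hr[1])
  }
  growing <- is.finite(slope) && slope > 0
  structure(list(tau_hr = if (growing) 1 / slope else NA_real_,
                 slope = slope, n = nrow(d), growing = growing),
            class = "doubling_fit")
}

#' @export
print.doubling_fit <- function(x, ...) {
  if (x$growing)
    cat(sprintf("<doubling_fit> tau = %.3f hr (n = %d)\n", x$tau_hr, x$n))
  else
    cat(sprintf("<doubling_fit> non-growing (slope %.3g, n = %d)\n",
                x$slope, x$n))
  invisible(x)
}

#' Predicted normalized cell count under exponential growth
#'
#' Closed-form prediction `b^(T / tau)` for the normalized count after `T`
#' hours, with per-cycle multiplication factor `b` and doubling period
#' `tau`. With `b = 2` every cell divides each cycle; `b = 2 - f` models a
#' persistent fraction `f` of cells failing to divide each cycle (e.g.
#' `b = 1.4` when 60% do not divide, `b = 1.7` when 30% do not).
#'
#' @param T Assay time (hr), >= 0.
#' @param b Per-cycle multiplication factor.
#' @param tau Doubling period (hr); default 20.72.
#' @return Predicted normalized count.
#' @export
predict_count <- function(T, b = 2, tau = 20.72) {
  if (any(T < 0)) stop("`T` must be non-negative")
  if (b <= 0 || tau <= 0) stop("`b` and `tau` must be positive")
  b^(T / tau)
}

#' Per-cycle factor for a non-dividing fraction
#'
#' Maps the fraction `f` of cells that fail to divide each cycle to the
#' effective per-cycle multiplication factor `b = 2 - f`.
#'
#' @param f Non-dividing fraction in `[0, 1]`.
#' @return The per-cycle factor `b`.
#' @export
fraction_to_factor <- function(f) {
  if (any(f < 0 | f > 1)) stop("`f` must lie in [0, 1]")
  2 - f
}
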