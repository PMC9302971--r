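#' Raw FRAP trace
#'
#' Timestamped intensities of the bleached ROI, an unbleached reference ROI,
#' and a cell-free background ROI, with the index of the first post-bleach
#' sample. Times are in seconds with the bleach event at t = 0 (pre-bleach
#' samples at t <= 0).
#'
#' @param times Acquisition times (s), strictly increasing.
#' @param bleached,unbleached,background Intensity vectors (a.u.), same
#'   length as `times`.
#' @param bleach_index Index (1-based) of the first post-bleach sample; at
#'   least one sample must precede it.
#' @return An object of class `frap_trace`.
#' @export
frap_trace <- function(times, bleached, unbleached, background, bleach_index) {
  n <- length(times)
  if (length(bleached) != n || length(unbleached) != n ||
      length(background) != n)
    stop("all trace channels must have the same length as `times`")
  if (n < 2L || any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (bleach_index < 2L || bleach_index > n)
    stop("`bleach_index` must leave at least one pre-bleach sample")
  structure(list(times = as.numeric(times), bleached = as.numeric(bleached),
                 unbleached = as.numeric(unbleached),
                 background = as.numeric(background),
                 bleach_index = as.integer(bleach_index)),
            class = "frap_trace")
}

#' @export
print.frap_trace <- function(x, ...) {
  cat(sprintf("<frap_trace> %d samples, bleach after t = %g s\n",
              length(x$times), x$times[x$bleach_index - 1L]))
  invisible(x)
}

#' Background-subtract and normalize a FRAP trace
#'
#' Subtracts the background intensity frame-by-frame from the bleached-ROI
#' intensity and normalizes to the background-subtracted intensity of the
#' first frame imaged, so the first sample is exactly 1. The normalization is
#' invariant under a common gain applied to both channels and under a common
#' offset added to both. By default the reference is the very first frame
#' (the acquisition convention); `reference = "prebleach_mean"` averages all
#' pre-bleach frames instead, for noisy traces.
#'
#' @param trace A [frap_trace()].
#' @param reference `"first"` (default) or `"prebleach_mean"`.
#' @return A list of class `normalized_trace`: `times`, `normalized`,
#'   `bleach_index`.
#' @export
normalize_trace <- function(trace, reference = c("first", "prebleach_mean")) {
  stopifnot(inherits(trace, "frap_trace"))
  reference <- match.arg(reference)
  signal <- trace$bleached - trace$background
  ref <- if (reference == "first") signal[1] else
    mean(signal[seq_len(trace$bleach_index - 1L)])
  if (!is.finite(ref) || ref <= 0)
    stop("non-positive reference signal: background >= bleached intensity ",
         "in the reference frame(s)")
  structure(list(times = trace$times, normalized = signal / ref,
                 bleach_index = trace$bleach_index),
            class = "normalized_trace")
}

#' Recovery percentage at a fixed time after bleaching
#'
#' The normalized intensity at the acquired sample nearest `t` seconds,
#' expressed in percent of the pre-bleach reference (e.g. recovery at 220 s).
#' No interpolation: the assay reports values at acquired timepoints. Times
#' before the first post-bleach sample are an error; on a tie the earlier
#' sample is used.
#'
#' @param ntrace A [normalize_trace()] result.
#' @param t Time after bleaching (s).
#' @return Recovery in percent.
#' @export
recovery_at <- function(ntrace, t) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  post <- seq(ntrace$bleach_index, length(ntrace$times))
  t_post <- ntrace$times[post]
  if (t < t_post[1])
    stop("t = ", t, " s precedes the first post-bleach sample (",
         t_post[1], " s)")
  dt <- abs(t_post - t)
  i <- post[which(dt == min(dt))[1]]
  100 * ntrace$normalized[i]
}

#' Immediately-post-bleach intensity percentage
#'
#' The normalized intensity at the first post-bleach sample, in percent of
#' the pre-bleach reference — the bleach-depth readout (e.g. "reduced to 18%
#' of initial intensity").
#'
#' @inheritParams recovery_at
#' @return Post-bleach intensity in percent.
#' @export
postbleach_fraction <- function(ntrace) {
  stopifnot(inherits(ntrace, "normalized_trace"))
  100 * ntrace$normalized[ntrace$bleach_index]
}
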