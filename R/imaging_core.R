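#' Calibrated fluorescence image
#'
#' Container for a single-channel grayscale image together with its physical
#' pixel size. All intensity measurements in the package operate on this
#' object, and every distance reported in micrometres is derived from pixel
#' coordinates via `pixel_size`.
#'
#' Coordinate convention: pixel indices are 0-based and a pixel's *center* sits
#' at integer coordinates, so the pixel at matrix position `[r, c]` has center
#' `(x, y) = (c - 1, r - 1)`. ROI geometry (points, circles, line segments) is
#' continuous in this coordinate system.
#'
#' @param pixels Numeric matrix of non-negative intensities (arbitrary units);
#'   rows index y, columns index x.
#' @param pixel_size Physical size of one pixel in micrometres per pixel.
#' @param channel Channel name (free text, e.g. `"DAPI"`, `"GFP"`).
#' @param frame_time Optional acquisition time of this frame (same unit as the
#'   parent time-lapse).
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_size, channel = "gray",
                             frame_time = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1 x 1")
  if (anyNA(pixels) || any(pixels < 0))
    stop("pixel intensities must be finite and non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      is.na(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/px)")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         channel = as.character(channel), frame_time = frame_time),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px, channel '%s'\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, x$channel))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$pixels)

#' Time-lapse image sequence
#'
#' An ordered sequence of [calibrated_image()] frames sharing dimensions and
#' calibration, with strictly increasing acquisition timestamps.
#'
#' @param frames List of `calibrated_image` objects.
#' @param timestamps Numeric vector of acquisition times, strictly increasing,
#'   one per frame (minutes or seconds depending on the assay).
#' @return An object of class `time_lapse`.
#' @export
time_lapse <- function(frames, timestamps) {
  if (!length(frames)) stop("a time-lapse needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "calibrated_image")))
    stop("all frames must be calibrated_image objects")
  d <- dim(frames[[1]]$pixels)
  ps <- frames[[1]]$pixel_size
  for (f in frames) {
    if (!identical(dim(f$pixels), d)) stop("frames have unequal dimensions")
    if (f$pixel_size != ps) stop("frames have unequal pixel sizes")
  }
  if (length(timestamps) != length(frames))
    stop("one timestamp per frame required")
  if (anyNA(timestamps) || any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps = as.numeric(timestamps)),
            class = "time_lapse")
}

#' @export
length.time_lapse <- function(x) length(x$frames)

#' @export
print.time_lapse <- function(x, ...) {
  cat(sprintf("<time_lapse> %d frames, t = %g..%g\n", length(x$frames),
              x$timestamps[1], x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' Point and circle regions of interest
#'
#' `point_roi()` marks a continuous position (e.g. a spindle pole or a
#' centromere) in 0-based pixel coordinates. `circle_roi()` describes a
#' circular measurement region with a physical radius in micrometres.
#'
#' @param x,y Continuous pixel coordinates (0-based, pixel centers at
#'   integers).
#' @return A `point_roi` object.
#' @export
point_roi <- function(x, y) {
  if (!is.finite(x) || !is.finite(y)) stop("ROI coordinates must be finite")
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "point_roi")
}

#' @param center A [point_roi()].
#' @param radius_um Circle radius in micrometres; must be positive.
#' @rdname point_roi
#' @export
circle_roi <- function(center, radius_um) {
  if (!inherits(center, "point_roi")) stop("`center` must be a point_roi")
  if (!is.finite(radius_um) || radius_um <= 0)
    stop("`radius_um` must be positive")
  structure(list(center = center, radius_um = as.numeric(radius_um)),
            class = "circle_roi")
}

in_bounds <- function(image, x, y) {
  x >= 0 & x <= ncol(image$pixels) - 1L & y >= 0 & y <= nrow(image$pixels) - 1L
}

#' Mean intensity inside a circular ROI
#'
#' Mean of the pixels whose centers fall within the circle (pixel-center
#' membership rule). This is the primitive used for FRAP ROI readout, where
#' small circular regions (e.g. area 0.865 um^2) are measured per frame.
#'
#' @param image A [calibrated_image()].
#' @param roi A [circle_roi()]; must lie fully inside the image and contain at
#'   least one pixel center.
#' @return Mean intensity (arbitrary units).
#' @export
roi_mean_intensity <- function(image, roi) {
  stopifnot(inherits(image, "calibrated_image"), inherits(roi, "circle_roi"))
  r_px <- roi$radius_um / image$pixel_size
  cx <- roi$center$x; cy <- roi$center$y
  if (cx - r_px < 0 || cy - r_px < 0 ||
      cx + r_px > ncol(image$pixels) - 1L || cy + r_px > nrow(image$pixels) - 1L)
    stop("circle ROI extends beyond the image")
  xs <- seq(floor(cx - r_px), ceiling(cx + r_px))
  ys <- seq(floor(cy - r_px), ceiling(cy + r_px))
  g <- expand.grid(x = xs, y = ys)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= r_px^2
  if (!any(keep))
    stop("circle ROI contains no pixel centers; enlarge the radius")
  mean(image$pixels[cbind(g$y[keep] + 1L, g$x[keep] + 1L)])
}

bilinear_sample <- function(pixels, x, y) {
  # x, y continuous 0-based; clamp to valid interpolation cell
  nx <- ncol(pixels); ny <- nrow(pixels)
  x0 <- pmin(pmax(floor(x), 0), nx - 2L)
  y0 <- pmin(pmax(floor(y), 0), ny - 2L)
  if (nx == 1L) x0 <- rep(0L, length(x))
  if (ny == 1L) y0 <- rep(0L, length(y))
  fx <- x - x0; fy <- y - y0
  i00 <- pixels[cbind(y0 + 1L, x0 + 1L)]
  i10 <- pixels[cbind(y0 + 1L, pmin(x0 + 2L, nx))]
  i01 <- pixels[cbind(pmin(y0 + 2L, ny), x0 + 1L)]
  i11 <- pixels[cbind(pmin(y0 + 2L, ny), pmin(x0 + 2L, nx))]
  (1 - fx) * (1 - fy) * i00 + fx * (1 - fy) * i10 +
    (1 - fx) * fy * i01 + fx * fy * i11
}

#' Sample an intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation along the segment from `p1` to
#' `p2`, endpoint-inclusive, at (approximately) one-pixel spacing: the number
#' of samples is `round(L/spacing) + 1` for segment length `L` px, so samples
#' are evenly spaced and the profile of the reversed segment is the exact
#' reverse of the forward profile. Positions are reported in micrometres from
#' `p1`.
#'
#' @param image A [calibrated_image()].
#' @param p1,p2 Distinct [point_roi()] endpoints inside the image.
#' @param spacing_px Target sample spacing in pixels (default 1).
#' @return A data frame of class `intensity_profile` with columns
#'   `position_um` and `intensity`.
#' @export
sample_line_profile <- function(image, p1, p2, spacing_px = 1) {
  stopifnot(inherits(image, "calibrated_image"),
            inherits(p1, "point_roi"), inherits(p2, "point_roi"))
  if (!in_bounds(image, p1$x, p1$y) || !in_bounds(image, p2$x, p2$y))
    stop("profile endpoints must lie inside the image")
  len_px <- sqrt((p2$x - p1$x)^2 + (p2$y - p1$y)^2)
  if (len_px == 0) stop("degenerate segment: p1 == p2")
  if (spacing_px <= 0) stop("`spacing_px` must be positive")
  n <- max(2L, as.integer(round(len_px / spacing_px)) + 1L)
  t <- seq(0, 1, length.out = n)
  vals <- bilinear_sample(image$pixels, p1$x + t * (p2$x - p1$x),
                          p1$y + t * (p2$y - p1$y))
  out <- data.frame(position_um = t * len_px * image$pixel_size,
                    intensity = vals)
  class(out) <- c("intensity_profile", "data.frame")
  attr(out, "pixel_size") <- image$pixel_size
  out
}

#' Gaussian-blur background subtraction
#'
#' Estimates the low-frequency background of an image as a wide Gaussian blur
#' of the image itself and subtracts it, clipping negative results to zero.
#' Used to sharpen spindle-pole and centromere markers before line profiling:
#' a point-like marker survives almost untouched while smooth background (and
#' the blurred copy of the marker itself, spread over ~sigma^2 pixels) is
#' removed.
#'
#' @param image A [calibrated_image()].
#' @param blur_sigma_px Standard deviation of the Gaussian blur in pixels
#'   (default 30).
#' @return A `calibrated_image` with the blurred background removed.
#' @export
blur_background_subtract <- function(image, blur_sigma_px = 30) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!is.finite(blur_sigma_px) || blur_sigma_px <= 0)
    stop("`blur_sigma_px` must be positive")
  px <- image$pixels
  # the blur kernel spans 2*ceiling(3*sigma)+1 px; pad small images by edge
  # replication so wide blurs remain defined, then crop back
  kernel <- 2L * ceiling(3 * blur_sigma_px) + 1L
  pr <- max(0L, ceiling((kernel - nrow(px)) / 2) + 1L)
  pc <- max(0L, ceiling((kernel - ncol(px)) / 2) + 1L)
  if (pr > 0L || pc > 0L) {
    ri <- pmin(pmax(seq_len(nrow(px) + 2L * pr) - pr, 1L), nrow(px))
    ci <- pmin(pmax(seq_len(ncol(px) + 2L * pc) - pc, 1L), ncol(px))
    padded <- px[ri, ci, drop = FALSE]
    bg <- as.matrix(EBImage::gblur(padded, sigma = blur_sigma_px,
                                   boundary = "replicate"))
    bg <- bg[pr + seq_len(nrow(px)), pc + seq_len(ncol(px)), drop = FALSE]
  } else {
    bg <- as.matrix(EBImage::gblur(px, sigma = blur_sigma_px,
                                   boundary = "replicate"))
  }
  out <- pmax(px - bg, 0)
  calibrated_image(out, image$pixel_size, image$channel, image$frame_time)
}

#' Background-subtracted mean intensity over a mask
#'
#' Mean signal in a thresholded region corrected for background measured in a
#' disjoint cell-free region: subtracting mean background times the mask area
#' from the mask's integrated density and dividing by the mask area, which is
#' algebraically the difference of the two means. This is the expression-level
#' readout (e.g. chromosome-bound motor intensity over a DAPI mask).
#'
#' @param image A [calibrated_image()].
#' @param signal_mask Logical matrix, same dimensions as the image; `TRUE`
#'   marks signal pixels.
#' @param background_mask Logical matrix marking a non-empty background region
#'   disjoint from `signal_mask`.
#' @return Background-corrected mean intensity (arbitrary units).
#' @export
background_subtracted_mean <- function(image, signal_mask, background_mask) {
  stopifnot(inherits(image, "calibrated_image"))
  if (!identical(dim(signal_mask), dim(image$pixels)) ||
      !identical(dim(background_mask), dim(image$pixels)))
    stop("masks must match the image dimensions")
  area <- sum(signal_mask)
  if (area == 0) stop("signal mask is empty")
  if (!any(background_mask)) stop("background region is empty")
  if (any(signal_mask & background_mask))
    stop("signal and background regions must be disjoint")
  integrated <- sum(image$pixels[signal_mask])
  mean_bg <- mean(image$pixels[background_mask])
  (integrated - mean_bg * area) / area
}

#' Write and read calibrated TIFF stacks
#'
#' `write_image_stack()` stores a [time_lapse()] (or a single
#' [calibrated_image()]) as a 16-bit multi-page grayscale TIFF, with the
#' calibration (pixel size, timestamps, channel, intensity scale) recorded in
#' a YAML sidecar `<path>.yml`, because baseline TIFF tags do not carry it
#' reliably. `read_image_stack()` restores the stack; an explicit
#' `pixel_size_um` (and `timestamps`) argument overrides the sidecar, and a
#' stack with neither sidecar nor explicit calibration is an error — never a
#' silent default.
#'
#' @param x A `time_lapse` or `calibrated_image`.
#' @param path Output TIFF path; the sidecar is written to `paste0(path, ".yml")`.
#' @return `write_image_stack()` returns `path` invisibly;
#'   `read_image_stack()` returns a `time_lapse`.
#' @export
write_image_stack <- function(x, path) {
  if (inherits(x, "calibrated_image")) x <- time_lapse(list(x), 0)
  stopifnot(inherits(x, "time_lapse"))
  scale <- max(vapply(x$frames, function(f) max(f$pixels), numeric(1)), 1e-12)
  pages <- lapply(x$frames, function(f) f$pixels / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(pixel_size_um = x$frames[[1]]$pixel_size,
               timestamps = as.numeric(x$timestamps),
               channel = x$frames[[1]]$channel,
               intensity_scale = scale)
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

#' @param path TIFF file to read.
#' @param pixel_size_um Optional calibration override (um/px).
#' @param timestamps Optional acquisition-time override, strictly increasing.
#' @param channel Optional channel-name override.
#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, pixel_size_um = NULL, timestamps = NULL,
                             channel = NULL) {
  if (!file.exists(path)) stop("cannot read image stack: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stop("TIFF pages have unequal dimensions")
  sidecar <- paste0(path, ".yml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  ps <- if (!is.null(pixel_size_um)) pixel_size_um else meta$pixel_size_um
  if (is.null(ps))
    stop("no calibration for ", path,
         ": supply `pixel_size_um` or provide a YAML sidecar")
  ts <- if (!is.null(timestamps)) timestamps else meta$timestamps
  if (is.null(ts)) ts <- seq_along(pages) - 1
  if (length(ts) != length(pages))
    stop("timestamp count does not match page count")
  if (any(diff(ts) <= 0)) stop("timestamps must be strictly increasing")
  ch <- if (!is.null(channel)) channel else
    if (!is.null(meta$channel)) meta$channel else "gray"
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  frames <- mapply(function(p, t)
    calibrated_image(p * scale, ps, ch, t), pages, ts, SIMPLIFY = FALSE)
  time_lapse(frames, ts)
}
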