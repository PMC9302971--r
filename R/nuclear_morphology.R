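#' Segment interphase nuclei from a DNA-stain image
#'
#' Otsu threshold, hole filling, connected-component labelling, and an area
#' filter in physical units. Objects touching the image border are flagged
#' (their shape is truncated) and excluded by default.
#'
#' @param dapi A [calibrated_image()] of a DNA stain; must not be constant.
#' @param min_area_um2,max_area_um2 Area filter bounds (um^2).
#' @param exclude_border Drop border-touching nuclei (default `TRUE`).
#' @return A list of per-nucleus lists, each with `mask` (logical matrix,
#'   full image size), `label`, and `touches_border`.
#' @export
segment_nuclei <- function(dapi, min_area_um2 = 10, max_area_um2 = 1e4,
                           exclude_border = TRUE) {
  stopifnot(inherits(dapi, "calibrated_image"))
  px <- dapi$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) stop("constant image: nothing to segment")
  sc <- (px - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(t(sc)))
  bw <- sc > th
  filled <- EBImage::fillHull(EBImage::Image(t(bw))) > 0
  lab <- EBImage::bwlabel(EBImage::Image(filled))
  labm <- t(as.matrix(lab))  # back to rows = y, cols = x
  n_obj <- max(labm)
  px_area <- dapi$pixel_size^2
  out <- list()
  for (k in seq_len(n_obj)) {
    mask <- labm == k
    area_um2 <- sum(mask) * px_area
    if (area_um2 < min_area_um2 || area_um2 > max_area_um2) next
    touches <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)])
    if (touches && exclude_border) next
    out[[length(out) + 1L]] <- list(mask = mask, label = k,
                                    touches_border = touches)
  }
  out
}

#' Solidity of a binary mask
#'
#' Ratio of the mask's pixel count to the pixel count of its filled convex
#' hull: 1 for convex shapes, below 1 for lobed or fragmented nuclei. The
#' hull is the convex hull of the mask's pixel centers, and its filled area
#' is the number of pixel centers on or inside that hull, counted by an
#' exact per-row scan of the convex cross-section, so the measure is
#' translation- and 90-degree-rotation invariant and never exceeds 1.
#'
#' @param mask Logical matrix (rows = y, cols = x); must be non-empty.
#' @return Solidity in `(0, 1]`.
#' @export
solidity <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) stop("`mask` must be a logical matrix")
  area <- sum(mask)
  if (area == 0) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  h <- grDevices::chull(pts)
  if (length(h) < 3L) return(1)  # collinear pixel set is convex
  hull <- pts[h, , drop = FALSE]
  area / hull_lattice_count(hull)
}

# Number of integer lattice points on or inside a convex polygon with integer
# vertices: for each lattice row, intersect every edge with the row and count
# the integers in the [min, max] cross-section (eps guards float round-off on
# boundary points).
hull_lattice_count <- function(hull) {
  eps <- 1e-9
  ys <- seq(ceiling(min(hull[, 2]) - eps), floor(max(hull[, 2]) + eps))
  xl <- rep(Inf, length(ys)); xr <- rep(-Inf, length(ys))
  n <- nrow(hull)
  for (i in seq_len(n)) {
    p <- hull[i, ]; q <- hull[i %% n + 1L, ]
    lo <- min(p[2], q[2]); hi <- max(p[2], q[2])
    j <- which(ys >= lo - eps & ys <= hi + eps)
    if (!length(j)) next
    if (abs(q[2] - p[2]) < eps) {
      xl[j] <- pmin(xl[j], p[1], q[1])
      xr[j] <- pmax(xr[j], p[1], q[1])
    } else {
      x <- p[1] + (ys[j] - p[2]) / (q[2] - p[2]) * (q[1] - p[1])
      xl[j] <- pmin(xl[j], x)
      xr[j] <- pmax(xr[j], x)
    }
  }
  sum(pmax(0, floor(xr + eps) - ceiling(xl - eps) + 1))
}

#' Per-nucleus morphology record
#'
#' @param mask Logical nucleus mask.
#' @param pixel_size um/px of the source image.
#' @param label,condition,experiment_id Identifiers carried into the record.
#' @param touches_border Border flag from segmentation.
#' @return One-row data frame: `label`, `condition`, `experiment_id`,
#'   `area_px`, `area_um2`, `convex_area_px`, `solidity`, `touches_border`.
#' @export
nucleus_record <- function(mask, pixel_size, label = NA, condition = NA,
                           experiment_id = NA, touches_border = FALSE) {
  s <- solidity(mask)
  area <- sum(mask)
  data.frame(label = label, condition = condition,
             experiment_id = experiment_id,
             area_px = area, area_um2 = area * pixel_size^2,
             convex_area_px = round(area / s),
             solidity = s, touches_border = touches_border)
}

#' Control-population solidity threshold
#'
#' The percentile of the control solidity distribution (default the 5th) used
#' as the cutoff below which a nucleus is called abnormally shaped. Computed
#' by linear interpolation between order statistics (`stats::quantile`
#' type 7); at least 20 control nuclei are required for the tail percentile
#' to be meaningful. Thresholds are dataset-relative: the control population
#' must come from the same experiment as the cells being classified.
#'
#' @param control_solidities Numeric vector of control-nucleus solidities.
#' @param percentile Percentile in (0, 100); default 5.
#' @return A list of class `solidity_threshold`: `value`, `percentile`,
#'   `control_n`.
#' @export
control_threshold <- function(control_solidities, percentile = 5) {
  v <- control_solidities[!is.na(control_solidities)]
  if (length(v) < 20L)
    stop("need at least 20 control nuclei for a percentile threshold (got ",
         length(v), ")")
  if (percentile <= 0 || percentile >= 100)
    stop("`percentile` must be in (0, 100)")
  if (any(v <= 0 | v > 1)) stop("solidities must lie in (0, 1]")
  structure(list(value = unname(stats::quantile(v, percentile / 100,
                                                type = 7)),
                 percentile = percentile, control_n = length(v)),
            class = "solidity_threshold")
}

#' @export
print.solidity_threshold <- function(x, ...) {
  cat(sprintf("<solidity_threshold> %gth percentile of %d controls = %.4f\n",
              x$percentile, x$control_n, x$value))
  invisible(x)
}

#' Classify nuclei against a control-derived solidity threshold
#'
#' A nucleus is abnormal iff its solidity is strictly below the threshold
#' value; ties count as normal. Returns per-condition counts, abnormal
#' fractions, and per-experiment median solidity.
#'
#' @param records Data frame with at least `solidity` and `condition`
#'   columns (e.g. rows from [nucleus_record()]); an `experiment_id` column
#'   is used for per-experiment medians when present.
#' @param threshold A [control_threshold()] result.
#' @return A list of class `classification_summary`: `per_nucleus` (the
#'   input plus an `abnormal` flag), `per_condition` (columns `condition`,
#'   `n`, `n_abnormal`, `fraction_abnormal`, `median_solidity`), and
#'   `threshold`.
#' @export
classify_nuclei <- function(records, threshold) {
  stopifnot(inherits(threshold, "solidity_threshold"))
  if (!all(c("solidity", "condition") %in% names(records)))
    stop("`records` needs `solidity` and `condition` columns")
  records$abnormal <- records$solidity < threshold$value
  agg <- lapply(split(records, records$condition), function(d) {
    data.frame(condition = d$condition[1], n = nrow(d),
               n_abnormal = sum(d$abnormal),
               fraction_abnormal = mean(d$abnormal),
               median_solidity = stats::median(d$solidity))
  })
  per_condition <- do.call(rbind, agg)
  rownames(per_condition) <- NULL
  structure(list(per_nucleus = records, per_condition = per_condition,
                 threshold = threshold),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("<classification_summary> threshold %.4f (%gth pct of %d controls)\n",
              x$threshold$value, x$threshold$percentile,
              x$threshold$control_n))
  print(x$per_condition)
  invisible(x)
}
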