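# Independent oracles and small fixture builders shared across tests.

make_image <- function(mat, pixel_size = 0.1, channel = "test") {
  calibrated_image(mat, pixel_size, channel)
}

# Per-pixel brute-force radial binning: loop over every pixel, accumulate
# into annuli [k*w, (k+1)*w). Deliberately written as an explicit loop so it
# shares no code path with radial_profile().
oracle_radial_profile <- function(image, pole, max_radius_um, bin_width_um) {
  n_bins <- floor(max_radius_um / bin_width_um + 1e-9)
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  px <- image$pixels
  for (r in seq_len(nrow(px))) {
    for (c in seq_len(ncol(px))) {
      d <- sqrt((c - 1 - pole$x)^2 + (r - 1 - pole$y)^2) * image$pixel_size
      k <- floor(d / bin_width_um)
      if (k < n_bins) {
        sums[k + 1] <- sums[k + 1] + px[r, c]
        counts[k + 1] <- counts[k + 1] + 1L
      }
    }
  }
  ifelse(counts > 0, sums / counts, NA_real_)
}

# Continuous-polygon solidity oracle: shoelace area over convex-hull area of
# dense boundary samples.
oracle_polygon_solidity <- function(poly) {
  shoelace <- function(x, y) {
    n <- length(x); j <- c(n, seq_len(n - 1L))
    abs(sum(x[j] * y - x * y[j])) / 2
  }
  hull <- poly[grDevices::chull(poly), , drop = FALSE]
  shoelace(poly[, 1], poly[, 2]) / shoelace(hull[, 1], hull[, 2])
}

# Rasterize an arbitrary polygon (um coordinates, centered near 0) by the
# pixel-center rule.
rasterize_polygon <- function(poly, pixel_size) {
  ext <- max(abs(poly)) + 2 * pixel_size
  half_n <- ceiling(ext / pixel_size)
  coords <- (-half_n:half_n) * pixel_size
  g <- cbind(x = rep(coords, times = length(coords)),
             y = rep(coords, each = length(coords)))
  inside <- mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), g + 0)
  mask <- matrix(FALSE, length(coords), length(coords))
  gi <- g[inside, , drop = FALSE]
  mask[cbind(match(gi[, "y"], coords), match(gi[, "x"], coords))] <- TRUE
  mask
}

# Two-Gaussian axis fixture: a 1-D style image whose every row is the same
# double-Gaussian profile, poles on a horizontal axis.
two_mass_image <- function(n = 256, pixel_size = 0.1, d_um = 10,
                           sigma_um = 0.5, peak = 1000) {
  c0 <- (n - 1) / 2
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), times = n), n, n)
  s <- sigma_um / pixel_size
  cl <- c0 - d_um / (2 * pixel_size); cr <- c0 + d_um / (2 * pixel_size)
  img <- peak * exp(-((x - cl)^2 + (y - c0)^2) / (2 * s^2)) +
    peak * exp(-((x - cr)^2 + (y - c0)^2) / (2 * s^2))
  make_image(img, pixel_size)
}

rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
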