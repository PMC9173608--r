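# largest 8-connected component of a mask, warning if others are dropped
largest_mask_component <- function(mask, warn_multiple = TRUE) {
  if (!any(mask)) stop_input("empty mask")
  L <- matrix(0L, nrow(mask), ncol(mask))
  L[mask] <- 1L
  comp <- label_components(L)
  if (max(comp) > 1L) {
    if (warn_multiple)
      warning("mask has ", max(comp),
              " connected components; keeping the largest")
    keep <- which.max(tabulate(comp))
    idx <- which(mask)
    mask <- matrix(FALSE, nrow(mask), ncol(mask))
    mask[idx[comp == keep]] <- TRUE
  }
  mask
}

# Extract the outer contour of a single-component mask as a closed
# sub-pixel polygon (marching squares at level 0.5).
mask_contour <- function(mask) {
  z <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)  # pad so contours close
  z[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.numeric(mask)
  cl <- grDevices::contourLines(x = seq_len(nrow(z)), y = seq_len(ncol(z)),
                                z = z, levels = 0.5)
  if (!length(cl)) stop_input("no contour found")
  areas <- vapply(cl, function(cc) {
    x <- cc$x; y <- cc$y
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, numeric(1))
  cc <- cl[[which.max(areas)]]
  cbind(x = cc$x, y = cc$y)
}

# resample a closed polygon to n points equally spaced by arc length
resample_contour <- function(pts, n) {
  if (!all(pts[1, ] == pts[nrow(pts), ])) pts <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  t <- c(0, cumsum(seg))
  total <- t[length(t)]
  tt <- seq(0, total, length.out = n + 1)[seq_len(n)]
  x <- stats::approx(t, pts[, 1], xout = tt)$y
  y <- stats::approx(t, pts[, 2], xout = tt)$y
  cbind(x = x, y = y)
}

# elliptical Fourier coefficients of an arc-length-uniform closed contour
efa_coefficients <- function(pts, harmonics) {
  n <- nrow(pts)
  fx <- stats::fft(pts[, 1]) / n
  fy <- stats::fft(pts[, 2]) / n
  h <- seq_len(harmonics)
  list(a0 = Re(fx[1]), c0 = Re(fy[1]),
       a = 2 * Re(fx[h + 1]), b = -2 * Im(fx[h + 1]),
       c = 2 * Re(fy[h + 1]), d = -2 * Im(fy[h + 1]))
}

efa_reconstruct <- function(cf, n_points) {
  tt <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  h <- seq_along(cf$a)
  C <- cos(outer(tt, h)); S <- sin(outer(tt, h))
  cbind(x = cf$a0 + C %*% cf$a + S %*% cf$b,
        y = cf$c0 + C %*% cf$c + S %*% cf$d)
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(p) {
  sum(sqrt(rowSums((p[c(2:nrow(p), 1), ] - p)^2)))
}

#' Outline shape features by elliptical Fourier analysis
#'
#' The outer contour of the (largest) mask component is extracted at
#' sub-pixel resolution, resampled uniformly by arc length, and decomposed
#' into `config$harmonics` harmonic ellipses. Gross shape lives in the
#' first harmonic, outline complexity in the higher ones. All four
#' features are invariant to translation, rotation and uniform scaling
#' (up to raster error).
#'
#' @param mask logical matrix (organism mask), or a [masked_image()].
#' @param config a [feature_config()].
#' @return Named numeric vector: `elongatedness` (major/minor axis ratio
#'   of the body's moment ellipse — the ellipse the first harmonic
#'   approximates, computed from second moments of the filled mask so a
#'   2:1 ellipse scores exactly 2), `circularity` (`4*pi*A/P^2` of the
#'   reconstructed outline), `convexity` (outline area over its convex
#'   hull's area), `outline_harmonic_power` (share of harmonic amplitude
#'   squared carried by harmonics >= 2).
#' @export
shape_features <- function(mask, config = feature_config()) {
  if (inherits(mask, "masked_image")) mask <- mask$mask
  mask <- largest_mask_component(mask)
  pts <- mask_contour(mask)
  pts <- resample_contour(pts, max(4L * config$harmonics,
                                   config$contour_points))
  cf <- efa_coefficients(pts, config$harmonics)

  idxm <- which(mask)
  coords <- cbind(((idxm - 1L) %% nrow(mask)) + 1L,
                  ((idxm - 1L) %/% nrow(mask)) + 1L)
  ev <- eigen(stats::cov(coords), symmetric = TRUE)$values
  elong <- sqrt(max(ev) / max(min(ev), .Machine$double.eps))

  rec <- efa_reconstruct(cf, config$contour_points)
  A <- polygon_area(rec)
  P <- polygon_perimeter(rec)
  hull <- rec[grDevices::chull(rec), , drop = FALSE]
  amp2 <- cf$a^2 + cf$b^2 + cf$c^2 + cf$d^2

  c(elongatedness = elong,
    circularity = 4 * pi * A / P^2,
    convexity = A / polygon_area(hull),
    outline_harmonic_power = sum(amp2[-1]) / sum(amp2))
}
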