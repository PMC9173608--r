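#' Procedural fish image specification
#'
#' Describes a synthetic fish: a superellipse body (horizontal major axis,
#' mouth to the left, tail to the right) with optional triangular fins and
#' vertical stripe bands, rendered on a white square canvas. The generator
#' stands in for photographic material so that every image feature has a
#' known ground truth.
#'
#' @param body_aspect major/minor axis ratio of the body ellipse, `>= 1`.
#' @param n_stripes number of vertical stripe bands (`>= 0`).
#' @param palette list of RGB triples in `[0, 1]`; the first entry is the
#'   base body colour, subsequent entries are cycled across stripes.
#' @param saturation_scale multiplier in `[0, 1]` applied to the HSV S
#'   channel of every organism pixel (1 leaves colours untouched).
#' @param lightness_contrast amplitude in `[0, 1]` of a vertical HSV-value
#'   gradient across the body (0 = flat lighting).
#' @param fin_profile one of `"none"`, `"caudal_only"`, `"full"`.
#' @param fin_scale positive multiplier on fin length and height
#'   (default 1).
#' @param slot_weights optional positive weights (length
#'   `2 * n_stripes + 1`) for the widths of the alternating base/stripe
#'   bands along the body; `NULL` gives equal widths.
#' @param canvas_px side of the square canvas in pixels.
#' @param seed integer seed (the renderer is deterministic; the seed is
#'   recorded so specs can be replayed through stochastic downstream steps).
#' @return An object of class `fish_spec`.
#' @export
fish_spec <- function(body_aspect = 1.8, n_stripes = 0,
                      palette = list(c(0.9, 0.6, 0.1)),
                      saturation_scale = 1, lightness_contrast = 0,
                      fin_profile = c("caudal_only", "none", "full"),
                      fin_scale = 1, slot_weights = NULL,
                      canvas_px = 500, seed = 1L) {
  fin_profile <- match.arg(fin_profile)
  if (!is.numeric(body_aspect) || body_aspect < 1)
    stop_input("`body_aspect` must be >= 1")
  if (n_stripes < 0 || n_stripes != round(n_stripes))
    stop_input("`n_stripes` must be a non-negative integer")
  if (!is.list(palette) || length(palette) < 1L)
    stop_input("`palette` must be a non-empty list of RGB triples")
  for (p in palette)
    if (length(p) != 3L || any(p < 0) || any(p > 1))
      stop_input("palette entries must be RGB triples in [0, 1]")
  if (saturation_scale < 0 || saturation_scale > 1)
    stop_input("`saturation_scale` must be in [0, 1]")
  if (lightness_contrast < 0 || lightness_contrast > 1)
    stop_input("`lightness_contrast` must be in [0, 1]")
  if (canvas_px < 32) stop_input("`canvas_px` must be at least 32")
  if (fin_scale <= 0 || fin_scale > 2) stop_input("`fin_scale` in (0, 2]")
  if (!is.null(slot_weights)) {
    if (length(slot_weights) != 2 * n_stripes + 1 || any(slot_weights <= 0))
      stop_input("`slot_weights` must be ", 2 * n_stripes + 1,
                 " positive values")
  }
  structure(list(body_aspect = body_aspect, n_stripes = as.integer(n_stripes),
                 palette = palette, saturation_scale = saturation_scale,
                 lightness_contrast = lightness_contrast,
                 fin_profile = fin_profile, fin_scale = fin_scale,
                 slot_weights = slot_weights,
                 canvas_px = as.integer(canvas_px),
                 seed = as.integer(seed)),
            class = "fish_spec")
}

# exact (unquantized) hexcone conversions, vectorized over n x 3 matrices
hsv_to_rgb_exact <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# vectorized point-in-triangle via barycentric sign tests
in_triangle <- function(px, py, v1, v2, v3) {
  s <- function(ax, ay, bx, by) (px - bx) * (ay - by) - (ax - bx) * (py - by)
  d1 <- s(v1[1], v1[2], v2[1], v2[2])
  d2 <- s(v2[1], v2[2], v3[1], v3[2])
  d3 <- s(v3[1], v3[2], v1[1], v1[2])
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}

#' Render a procedural fish image
#'
#' Deterministic given its spec: the body is a superellipse (exponent 2.5),
#' fins are triangles, stripes are equal-width vertical bands alternating
#' palette colours, and the background is exactly white. Saturation and
#' lightness adjustments are applied in HSV space to organism pixels only.
#'
#' The returned image carries a `ground_truth` attribute with the palette
#' index of every pixel (0 = background), used by segmentation oracles.
#'
#' @param spec a [fish_spec()].
#' @return A [masked_image()] with attribute `ground_truth`.
#' @export
generate_fish_image <- function(spec) {
  stopifnot(inherits(spec, "fish_spec"))
  n <- spec$canvas_px
  cx <- 0.45 * n; cy <- 0.5 * n
  a <- 0.38 * n
  b <- a / spec$body_aspect
  if (b < 2)
    stop_input("canvas too small to hold body at requested aspect: ",
               "minor semi-axis would be ", signif(b, 3), " px")

  xs <- matrix(rep(seq_len(n), each = n), n)  # column index
  ys <- matrix(rep(seq_len(n), times = n), n) # row index
  e <- 2.5
  body <- (abs(xs - cx) / a)^e + (abs(ys - cy) / b)^e <= 1

  fins <- matrix(FALSE, n, n)
  px <- as.vector(xs); py <- as.vector(ys)
  clamp_y <- function(y) min(max(y, 2), n - 1)
  fs <- spec$fin_scale
  if (spec$fin_profile %in% c("caudal_only", "full")) {
    x0 <- cx + 0.95 * a; ftl <- 0.35 * a * fs; fh <- 0.6 * b * fs
    caudal <- xs >= x0 & xs <= min(x0 + ftl, n - 1) &
      abs(ys - cy) <= fh * (xs - x0) / ftl
    fins <- fins | caudal
  }
  if (spec$fin_profile == "full") {
    dor <- in_triangle(px, py,
                       c(cx - 0.30 * a, clamp_y(cy - 0.60 * b)),
                       c(cx + 0.20 * a, clamp_y(cy - 0.60 * b)),
                       c(cx - 0.05 * a, clamp_y(cy - (0.6 + fs) * b)))
    ana <- in_triangle(px, py,
                       c(cx - 0.30 * a, clamp_y(cy + 0.60 * b)),
                       c(cx + 0.20 * a, clamp_y(cy + 0.60 * b)),
                       c(cx - 0.05 * a, clamp_y(cy + (0.6 + fs) * b)))
    fins <- fins | matrix(dor | ana, n, n)
  }
  mask <- body | fins

  # palette index per pixel: 1 = base colour, stripes cycle entries 2..np
  np <- length(spec$palette)
  lab <- matrix(0L, n, n)
  lab[mask] <- 1L
  if (spec$n_stripes > 0 && np >= 2) {
    ns <- spec$n_stripes
    w <- spec$slot_weights %||% rep(1, 2 * ns + 1)
    edges <- (cx - a) + 2 * a * c(0, cumsum(w)) / sum(w)
    for (i in seq_len(ns)) {
      lo <- edges[2 * i]; hi <- edges[2 * i + 1]  # even slots are stripes
      stripe <- body & xs >= lo & xs < hi
      lab[stripe] <- ((i - 1L) %% (np - 1L)) + 2L
    }
  }

  pixels <- array(1, dim = c(n, n, 3))
  pal <- do.call(rbind, spec$palette)
  idx <- which(lab > 0L)
  cols <- pal[lab[idx], , drop = FALSE]
  if (spec$saturation_scale < 1 || spec$lightness_contrast > 0) {
    hsv0 <- grDevices::rgb2hsv(t(cols), maxColorValue = 1)
    s <- hsv0["s", ] * spec$saturation_scale
    v <- hsv0["v", ]
    if (spec$lightness_contrast > 0) {
      rows <- ys[idx]
      rng <- range(rows)
      g <- if (diff(rng) > 0) (rows - rng[1]) / diff(rng) else rep(0.5, length(rows))
      v <- pmin(1, pmax(0, v * (1 - spec$lightness_contrast / 2 +
                                  spec$lightness_contrast * g)))
    }
    # exact float conversion: no 8-bit quantization jitter in S or V
    cols <- hsv_to_rgb_exact(hsv0["h", ], pmin(1, pmax(0, s)), v)
  }
  for (ch in 1:3) {
    plane <- pixels[, , ch]
    plane[idx] <- cols[, ch]
    pixels[, , ch] <- plane
  }

  img <- masked_image(pixels, mask)
  attr(img, "ground_truth") <- list(color_label = lab, spec = spec)
  img
}
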