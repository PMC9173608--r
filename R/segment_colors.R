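# sRGB (in [0,1]) -> CIELAB under D65, via grDevices::convertColor
rgb_to_lab <- function(rgb) {
  grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
}

# HSV channels (each in [0,1]) for an n x 3 RGB matrix
rgb_to_hsv_mat <- function(rgb) {
  t(grDevices::rgb2hsv(t(rgb), maxColorValue = 1))
}

#' Feature-extraction configuration
#'
#' @param k_max largest number of colour clusters considered (in `[1, 10]`).
#' @param tau_uniform total CIELAB standard deviation below which an image
#'   is declared uniform (k = 1); default 2 CIELAB units.
#' @param n_restarts K-means restarts per k.
#' @param harmonics number of elliptical Fourier harmonics.
#' @param contour_points number of points sampled on the reconstructed
#'   outline.
#' @param min_patch_px patches smaller than this are merged into their
#'   largest neighbouring patch (raster-noise suppression).
#' @param max_kmeans_px,max_silhouette_px pixel subsample caps for the
#'   K-means fit and the silhouette model-selection step.
#' @param seed integer seed controlling the segmentation subsamples and
#'   K-means initialization.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(k_max = 10, tau_uniform = 2, n_restarts = 10,
                           harmonics = 20, contour_points = 512,
                           min_patch_px = 10, max_kmeans_px = 5000,
                           max_silhouette_px = 1000, seed = 1L) {
  if (k_max < 1 || k_max > 10) stop_input("`k_max` must be in [1, 10]")
  structure(list(k_max = as.integer(k_max), tau_uniform = tau_uniform,
                 n_restarts = as.integer(n_restarts),
                 harmonics = as.integer(harmonics),
                 contour_points = as.integer(contour_points),
                 min_patch_px = as.integer(min_patch_px),
                 max_kmeans_px = as.integer(max_kmeans_px),
                 max_silhouette_px = as.integer(max_silhouette_px),
                 seed = as.integer(seed)),
            class = "feature_config")
}

#' Segment organism colours by K-means in CIELAB space
#'
#' Masked pixels are converted to CIELAB (sRGB companding, D65 white
#' point) and clustered by K-means for each candidate k; the number of
#' colours is chosen by maximum mean silhouette width, with k = 1 declared
#' when the total CIELAB standard deviation falls below
#' `config$tau_uniform`. For large masks, K-means runs on a seeded pixel
#' subsample and all pixels are then assigned to the nearest centroid.
#'
#' @param img a [masked_image()].
#' @param config a [feature_config()].
#' @return Object of class `color_segmentation`: list with `labels`
#'   (integer cluster per masked pixel, aligned with `which(img$mask)`),
#'   `k`, `centroids` (k x 3 CIELAB matrix), `mask`.
#' @export
segment_colors <- function(img, config = feature_config()) {
  stopifnot(inherits(img, "masked_image"))
  idx <- which(img$mask)
  if (length(idx) < config$k_max)
    stop_input("mask smaller than k_max pixels")
  lab <- rgb_to_lab(masked_rgb(img))
  n <- nrow(lab)

  sd_tot <- sqrt(sum(apply(lab, 2, stats::var)))
  if (is.na(sd_tot) || sd_tot < config$tau_uniform) {
    return(structure(list(labels = rep(1L, n), k = 1L,
                          centroids = matrix(colMeans(lab), 1,
                                             dimnames = list(NULL, colnames(lab))),
                          mask = img$mask),
                     class = "color_segmentation"))
  }

  with_seed(config$seed, {
    fit_idx <- if (n > config$max_kmeans_px)
      sample.int(n, config$max_kmeans_px) else seq_len(n)
    sub <- lab[fit_idx, , drop = FALSE]
    n_uni <- nrow(unique(sub))
    ks <- seq(2L, min(config$k_max, n_uni))
    sil_idx <- if (nrow(sub) > config$max_silhouette_px)
      sample.int(nrow(sub), config$max_silhouette_px) else seq_len(nrow(sub))
    dsub <- stats::dist(sub[sil_idx, , drop = FALSE])
    best <- NULL; best_sil <- -Inf
    for (k in ks) {
      km <- tryCatch(
        stats::kmeans(sub, centers = k, nstart = config$n_restarts,
                      iter.max = 50),
        error = function(e) NULL)
      if (is.null(km)) next
      cl <- km$cluster[sil_idx]
      if (length(unique(cl)) < 2) next
      sil <- mean(cluster::silhouette(cl, dsub)[, 3])
      if (sil > best_sil) { best_sil <- sil; best <- km }
    }
    if (is.null(best))
      stop_input("k-means failed for every candidate k")
    # assign every masked pixel to its nearest centroid
    cen <- best$centers
    d2 <- outer(rowSums(lab^2), rep(1, nrow(cen))) -
      2 * lab %*% t(cen) + outer(rep(1, n), rowSums(cen^2))
    labels <- max.col(-d2)
    used <- sort(unique(labels))
    labels <- match(labels, used)
    structure(list(labels = as.integer(labels), k = length(used),
                   centroids = cen[used, , drop = FALSE], mask = img$mask),
              class = "color_segmentation")
  })
}

#' @export
print.color_segmentation <- function(x, ...) {
  cat(sprintf("<color_segmentation: k = %d over %d pixels>\n",
              x$k, length(x$labels)))
  invisible(x)
}

#' Colour-heterogeneity features
#'
#' @param seg a [segment_colors()] result.
#' @return Named numeric vector: `k_colors` (chosen cluster count),
#'   `color_entropy` (Shannon entropy of cluster pixel proportions, nats),
#'   `mean_centroid_distance` (mean pairwise CIELAB distance between
#'   cluster centroids, Delta-E), `dominant_color_share` (largest cluster
#'   proportion).
#' @export
color_features <- function(seg) {
  stopifnot(inherits(seg, "color_segmentation"))
  p <- tabulate(seg$labels, seg$k) / length(seg$labels)
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  mcd <- if (seg$k > 1) mean(stats::dist(seg$centroids)) else 0
  c(k_colors = as.numeric(seg$k), color_entropy = entropy,
    mean_centroid_distance = mcd, dominant_color_share = max(p))
}
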