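# Connected components of equal-label masked pixels (8-connectivity).
# `labels_full` is an H x W integer matrix, 0 = background.
# Returns integer component membership for pixels in `which(labels_full > 0)`.
label_components <- function(labels_full) {
  idx <- which(labels_full > 0L)
  n <- length(idx)
  H <- nrow(labels_full)
  vid <- integer(length(labels_full))
  vid[idx] <- seq_len(n)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  W <- ncol(labels_full)
  for (s in shifts) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    j <- (c2[ok] - 1L) * H + r2[ok]
    i <- idx[ok]
    keep <- labels_full[j] == labels_full[i]  # same cluster, both masked
    edges[[length(edges) + 1L]] <- cbind(vid[i[keep]], vid[j[keep]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el) && nrow(el))
    g <- igraph::add_edges(g, t(el))
  as.integer(igraph::components(g)$membership)
}

# Build the full-canvas label matrix from a segmentation
segmentation_label_matrix <- function(seg) {
  L <- matrix(0L, nrow(seg$mask), ncol(seg$mask))
  L[which(seg$mask)] <- seg$labels
  L
}

# adjacent in-mask 4-neighbour pixel pairs (linear indices), one per edge
mask_adjacent_pairs <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  idx <- which(mask)
  rows <- ((idx - 1L) %% H) + 1L
  cols <- ((idx - 1L) %/% H) + 1L
  out <- list()
  for (s in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- rows + s[1]; c2 <- cols + s[2]
    ok <- r2 <= H & c2 <= W
    j <- (c2[ok] - 1L) * H + r2[ok]
    keep <- mask[j]
    out[[length(out) + 1L]] <- cbind(idx[ok][keep], j[keep])
  }
  do.call(rbind, out)
}

#' Colour-pattern geometry features
#'
#' Patches are 8-connected components of equal-colour pixels; patches
#' smaller than `config$min_patch_px` are merged into their largest
#' neighbouring patch to suppress raster noise.
#'
#' @param seg a [segment_colors()] result.
#' @param img the [masked_image()] the segmentation came from.
#' @param config a [feature_config()].
#' @return Named numeric vector: `patch_count` (total number of patches),
#'   `pattern_repetition` (mean patches per colour cluster),
#'   `boundary_sharpness` (mean CIELAB contrast, Delta-E, across adjacent
#'   pixel pairs straddling two different colour clusters; 0 when k = 1),
#'   `patch_area_sd` (population SD of patch pixel areas),
#'   `boundary_fractal_dim` (box-counting dimension of the patch-outline
#'   pixel set).
#' @export
pattern_features <- function(seg, img, config = feature_config()) {
  stopifnot(inherits(seg, "color_segmentation"), inherits(img, "masked_image"))
  L <- segmentation_label_matrix(seg)
  idx <- which(seg$mask)
  comp <- label_components(L)

  # merge undersized patches into their largest neighbour
  sizes <- tabulate(comp)
  small <- which(sizes < config$min_patch_px & sizes > 0)
  if (length(small)) {
    pairs <- mask_adjacent_pairs(seg$mask)
    v <- integer(length(L)); v[idx] <- comp
    ci <- v[pairs[, 1]]; cj <- v[pairs[, 2]]
    cross <- ci != cj
    for (sc in small) {
      nb <- c(cj[cross & ci == sc], ci[cross & cj == sc])
      if (!length(nb)) next
      target <- as.integer(names(which.max(tapply(nb, nb, length))))
      # adopt the neighbour patch's colour cluster
      L[idx[comp == sc]] <- L[idx[comp == target][1]]
    }
    comp <- label_components(L)
    sizes <- tabulate(comp)
  }

  k_eff <- length(unique(L[idx]))
  n_patches <- max(comp)
  lab_px <- rgb_to_lab(masked_rgb(img))

  pairs <- mask_adjacent_pairs(seg$mask)
  v <- integer(length(L)); v[idx] <- seq_along(idx)
  li <- L[pairs[, 1]]; lj <- L[pairs[, 2]]
  cross <- li != lj
  sharpness <- if (any(cross)) {
    d <- lab_px[v[pairs[cross, 1]], , drop = FALSE] -
      lab_px[v[pairs[cross, 2]], , drop = FALSE]
    mean(sqrt(rowSums(d^2)))
  } else 0

  # inter-patch boundaries only (consistent with boundary_sharpness);
  # a single-colour fish has no pattern boundary and scores the floor 1
  boundary <- interpatch_boundary_pixels(L)
  fdim <- box_counting_dim(boundary, dim(L))

  c(patch_count = as.numeric(n_patches),
    pattern_repetition = n_patches / k_eff,
    boundary_sharpness = sharpness,
    patch_area_sd = sd_pop(sizes[sizes > 0]),
    boundary_fractal_dim = fdim)
}

# masked pixels whose 4-neighbourhood contains a *different* colour label
# (background does not count: the fish outline is shape, not pattern)
interpatch_boundary_pixels <- function(L) {
  H <- nrow(L); W <- ncol(L)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- L
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb_diff <- function(nb) nb != core & nb > 0L
  diff_any <- nb_diff(pad[1:H, 2:(W + 1)]) |
    nb_diff(pad[3:(H + 2), 2:(W + 1)]) |
    nb_diff(pad[2:(H + 1), 1:W]) |
    nb_diff(pad[2:(H + 1), 3:(W + 2)])
  which(core > 0L & diff_any)
}

# Box-counting estimate of the fractal dimension of a pixel set. Box
# sizes are fractions of the set's bounding-box extent, so the estimate
# is invariant to object scale (a dimension should be scale-free).
box_counting_dim <- function(lin_idx, dims,
                             fractions = 1 / c(4, 8, 16, 32, 64)) {
  if (length(lin_idx) < 2L) return(1)
  H <- dims[1]
  rows <- ((lin_idx - 1L) %% H) + 1L
  cols <- ((lin_idx - 1L) %/% H) + 1L
  extent <- max(max(rows) - min(rows), max(cols) - min(cols)) + 1L
  sizes <- unique(pmax(1, round(extent * fractions)))
  sizes <- sizes[sizes >= 1 & sizes <= extent / 2]
  if (length(sizes) < 2L) return(1)
  r0 <- rows - min(rows); c0 <- cols - min(cols)
  counts <- vapply(sizes, function(s) {
    length(unique(r0 %/% s * 1e6 + c0 %/% s))
  }, numeric(1))
  unname(stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[2])
}

#' Gaussian blur of a masked image
#'
#' Separable Gaussian filter applied to each RGB plane (edge-renormalized);
#' the mask is unchanged. Used to construct soft-edged variants of
#' hard-edged synthetic patterns.
#'
#' @param img a [masked_image()].
#' @param sigma Gaussian standard deviation in pixels.
#' @return A blurred [masked_image()].
#' @export
gaussian_blur <- function(img, sigma = 3) {
  stopifnot(inherits(img, "masked_image"), sigma > 0)
  n <- nrow(img$mask); m <- ncol(img$mask)
  kern_mat <- function(size) {
    K <- matrix(0, size, size)
    r <- ceiling(3 * sigma)
    for (i in seq_len(size)) {
      j <- max(1, i - r):min(size, i + r)
      w <- stats::dnorm(j - i, sd = sigma)
      K[j, i] <- w / sum(w)
    }
    K
  }
  Kr <- kern_mat(n); Kc <- kern_mat(m)
  px <- img$pixels
  # kernel columns hold output-pixel weights: rows mix via t(Kr), cols via Kc
  for (ch in 1:3) px[, , ch] <- crossprod(Kr, px[, , ch]) %*% Kc
  px[px < 0] <- 0; px[px > 1] <- 1
  masked_image(px, img$mask)
}
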