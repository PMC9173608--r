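#' PCA of standardized image features
#'
#' Columns are centred and scaled to unit variance before the rotation;
#' a constant column cannot be scaled and raises an error naming it.
#'
#' @param features numeric matrix or data.frame (rows = images); must have
#'   at least as many rows as columns.
#' @param n_components number of components to retain.
#' @return Object of class `pca_model`: `scores` (n x n_components),
#'   `loadings`, `var_fraction` (all components; sums to 1), `center`,
#'   `scale`, `n_components`.
#' @export
fit_pca <- function(features, n_components = 5) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop_input("features must be numeric")
  if (nrow(X) < ncol(X))
    stop_input("need at least as many rows as columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_input("constant column(s): ",
               paste(colnames(X)[sds == 0], collapse = ", "))
  n_components <- min(n_components, ncol(X))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x[, seq_len(n_components), drop = FALSE],
                 loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
                 var_fraction = vf, center = pc$center, scale = pc$scale,
                 n_components = n_components),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d components, %.1f%% variance>\n",
              x$n_components,
              100 * sum(x$var_fraction[seq_len(x$n_components)])))
  invisible(x)
}

# Indices of convex-hull vertices of a point cloud. Exact for d <= 2;
# for d > 2 vertices are recovered by support-function sampling: the
# argmax of a linear functional is always a hull vertex, so every index
# returned is genuine (some low-curvature vertices may be missed).
hull_vertex_indices <- function(X, n_directions = 5000, seed = 1L) {
  d <- ncol(X)
  if (d == 1L) return(unique(c(which.min(X[, 1]), which.max(X[, 1]))))
  if (d == 2L) return(grDevices::chull(X))
  with_seed(seed, {
    U <- matrix(stats::rnorm(n_directions * d), ncol = d)
    U <- rbind(U, diag(d), -diag(d))
    U <- U / sqrt(rowSums(U^2))
    sort(unique(max.col(tcrossprod(U, X))))
  })
}

#' Select a survey image set by convex-hull stratification
#'
#' Reproduces the survey-design stage: in the retained principal-component
#' space, `n_vertex` images are drawn near the vertices of the convex hull
#' of the cloud (k-nearest neighbours per vertex, sampled round-robin
#' across vertices) and `n_fill` are drawn uniformly from the remaining
#' volume. The two strata never overlap.
#'
#' @param pca a [fit_pca()] model (or a bare score matrix).
#' @param n_vertex images to draw from the hull-vertex stratum.
#' @param n_fill images to draw uniformly from the complement.
#' @param seed integer seed.
#' @return List with `selected` (row indices), `vertex_ids`, `fill_ids`,
#'   `hull_vertices`, and flag `degenerate_hull`.
#' @export
select_survey_set <- function(pca, n_vertex, n_fill, seed = 1L) {
  X <- if (inherits(pca, "pca_model")) pca$scores else as.matrix(pca)
  n <- nrow(X)
  if (n_vertex + n_fill > n)
    stop_input("requested more images than available")
  if (n_vertex + n_fill == n)
    return(list(selected = seq_len(n), vertex_ids = integer(0),
                fill_ids = seq_len(n), hull_vertices = integer(0),
                degenerate_hull = FALSE))

  ctr <- sweep(X, 2, colMeans(X))
  degenerate <- qr(ctr)$rank < ncol(X)
  if (degenerate) {
    warning("degenerate (collinear) point cloud; ",
            "falling back to per-axis extreme points")
    hv <- sort(unique(unlist(lapply(seq_len(ncol(X)), function(j)
      c(which.min(X[, j]), which.max(X[, j]))))))
  } else {
    hv <- hull_vertex_indices(X, seed = seed)
  }

  with_seed(seed, {
    k <- ceiling(n_vertex / length(hv))
    # per-vertex candidate lists: the k nearest neighbours of each vertex
    cand <- lapply(hv, function(v) {
      d <- sqrt(colSums((t(X) - X[v, ])^2))
      order(d)[seq_len(min(k + 1L, n))]  # includes the vertex itself
    })
    vertex_ids <- integer(0)
    ord <- sample(seq_along(cand))  # seeded vertex order
    pos <- rep(1L, length(cand))
    while (length(vertex_ids) < n_vertex) {
      advanced <- FALSE
      for (ci in ord) {
        if (length(vertex_ids) >= n_vertex) break
        while (pos[ci] <= length(cand[[ci]])) {
          pick <- cand[[ci]][pos[ci]]
          pos[ci] <- pos[ci] + 1L
          if (!(pick %in% vertex_ids)) {
            vertex_ids <- c(vertex_ids, pick)
            advanced <- TRUE
            break
          }
        }
      }
      if (!advanced) {
        # candidate balls exhausted: widen every list
        k <- 2L * k
        cand <- lapply(hv, function(v) {
          d <- sqrt(colSums((t(X) - X[v, ])^2))
          order(d)[seq_len(min(k + 1L, n))]
        })
        pos <- rep(1L, length(cand))
      }
    }
    rest <- setdiff(seq_len(n), vertex_ids)
    fill_ids <- sort(sample(rest, n_fill))
    list(selected = sort(c(vertex_ids, fill_ids)),
         vertex_ids = sort(vertex_ids), fill_ids = fill_ids,
         hull_vertices = hv, degenerate_hull = degenerate)
  })
}

# 99% normal-theory confidence ellipse: center, covariance, chi-square radius
fit_ellipse99 <- function(scores) {
  if (nrow(scores) < 3L) stop_input("need >= 3 points per group")
  S <- stats::cov(scores)
  if (abs(det(S)) < 1e-12) stop_input("degenerate ellipse: singular covariance")
  list(mu = colMeans(scores), Sinv = solve(S), r2 = stats::qchisq(0.99, df = 2))
}

in_ellipse <- function(pts, e) {
  d <- sweep(pts, 2, e$mu)
  rowSums((d %*% e$Sinv) * d) <= e$r2
}

#' Representativeness check: 99% ellipse overlap on PC1-PC2
#'
#' Fits 99% normal-theory confidence ellipses to the selected subset and
#' to the full set on the first two component scores, and reports their
#' Jaccard overlap area(intersection)/area(union), estimated by seeded
#' Monte-Carlo integration.
#'
#' @param selected_scores,all_scores matrices with >= 2 columns (only the
#'   first two are used) and >= 3 rows each.
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed.
#' @return Overlap fraction in `[0, 1]`.
#' @export
coverage_check <- function(selected_scores, all_scores, n_mc = 1e5,
                           seed = 1L) {
  s1 <- as.matrix(selected_scores)[, 1:2, drop = FALSE]
  s2 <- as.matrix(all_scores)[, 1:2, drop = FALSE]
  e1 <- fit_ellipse99(s1); e2 <- fit_ellipse99(s2)
  # common bounding box from both ellipses' extents
  ext <- function(e) {
    S <- solve(e$Sinv)
    half <- sqrt(diag(S) * e$r2)
    rbind(e$mu - half, e$mu + half)
  }
  b <- rbind(ext(e1), ext(e2))
  lo <- apply(b, 2, min); hi <- apply(b, 2, max)
  with_seed(seed, {
    pts <- cbind(stats::runif(n_mc, lo[1], hi[1]),
                 stats::runif(n_mc, lo[2], hi[2]))
    i1 <- in_ellipse(pts, e1); i2 <- in_ellipse(pts, e2)
    un <- sum(i1 | i2)
    if (un == 0) return(0)
    sum(i1 & i2) / un
  })
}
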