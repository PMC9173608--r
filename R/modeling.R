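#' Correlation filter for redundant features
#'
#' Builds the graph of feature pairs with `|Pearson r| >= threshold`,
#' takes its transitive closure (connected components), and keeps from
#' each correlated group only the feature whose absolute correlation with
#' the response is largest. Constant features are dropped with a warning.
#'
#' @param features numeric matrix or data.frame of candidate features.
#' @param response numeric vector aligned to rows.
#' @param threshold absolute-correlation grouping threshold (default 0.7).
#' @return Character vector of retained feature names, in original
#'   column order.
#' @export
correlation_filter <- function(features, response, threshold = 0.7) {
  X <- as.matrix(features)
  if (nrow(X) != length(response))
    stop_input("response must align with feature rows")
  sds <- apply(X, 2, stats::sd)
  # numerically degenerate columns count as constant
  const <- sds <= 1e-8 * (abs(colMeans(X)) + 1)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X) == 0L) return(character(0))
  R <- abs(stats::cor(X))
  ry <- abs(stats::cor(X, response))[, 1]
  A <- R >= threshold
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  grp <- igraph::components(g)$membership
  keep <- vapply(split(seq_len(ncol(X)), grp),
                 function(ix) ix[which.max(ry[ix])], integer(1))
  colnames(X)[sort(keep)]
}

#' Feature model with ordered entry and backward elimination
#'
#' Terms enter the linear model in decreasing order of their independent
#' contribution (univariate r-squared with the response); the least
#' significant term with `p > alpha` is then dropped repeatedly until
#' every remaining term is significant. Features are standardized so the
#' fitted coefficients are directly comparable in magnitude.
#'
#' @param features numeric matrix/data.frame (already correlation-filtered).
#' @param response numeric vector.
#' @param alpha two-sided significance level for retention (default 0.05).
#' @return Object of class `feature_model`: `terms` (retained names),
#'   `coefficients` (data.frame term/estimate/se/p, scaled scale), `r2`,
#'   `elimination_trace` (names in drop order), `fit` (the final `lm`).
#' @export
fit_feature_model <- function(features, response, alpha = 0.05) {
  X <- as.matrix(features)
  if (nrow(X) <= ncol(X) + 1L)
    stop_input("need n > p + 1 observations")
  Xs <- scale(X)
  qx <- qr(Xs)
  if (qx$rank < ncol(Xs))
    stop_input("rank-deficient design; collinear term(s): ",
               paste(colnames(Xs)[-seq_len(qx$rank)], collapse = ", "))
  r2_uni <- apply(Xs, 2, function(x) stats::cor(x, response)^2)
  ord <- order(r2_uni, decreasing = TRUE)
  terms <- colnames(Xs)[ord]
  df <- as.data.frame(Xs)
  df$.y <- response
  trace <- character(0)
  repeat {
    fml <- stats::reformulate(terms, response = ".y")
    fit <- stats::lm(fml, data = df)
    ct <- summary(fit)$coefficients
    p <- ct[-1, 4]  # drop intercept
    if (!length(p) || max(p) <= alpha) break
    worst <- names(which.max(p))
    trace <- c(trace, worst)
    terms <- setdiff(terms, worst)
    if (!length(terms)) { fit <- stats::lm(.y ~ 1, data = df); break }
  }
  ct <- summary(fit)$coefficients
  keep <- setdiff(rownames(ct), "(Intercept)")
  structure(list(
    terms = terms,
    coefficients = data.frame(term = keep,
                              estimate = ct[keep, 1], se = ct[keep, 2],
                              p = ct[keep, 4], row.names = NULL),
    r2 = summary(fit)$r.squared,
    elimination_trace = trace,
    alpha = alpha, fit = fit), class = "feature_model")
}

#' @export
print.feature_model <- function(x, ...) {
  cat(sprintf("<feature_model: %d terms, r2 = %.3f>\n",
              length(x$terms), x$r2))
  print(x$coefficients)
  invisible(x)
}

#' Biplot projection of the retained model features
#'
#' PCA of the standardized retained features, giving image coordinates
#' and feature loadings for a biplot.
#'
#' @param model a [fit_feature_model()] result.
#' @param features the feature table the model was fitted on.
#' @return A `pca_model` restricted to the retained terms.
#' @export
project_pca <- function(model, features) {
  stopifnot(inherits(model, "feature_model"))
  fit_pca(as.matrix(features)[, model$terms, drop = FALSE],
          n_components = min(length(model$terms), 5L))
}

#' Species-grouped cross-validation plan
#'
#' Species are shuffled and dealt round-robin to `k` folds so that all
#' images of a species share a fold (no species-level leakage) and fold
#' sizes differ by at most one species.
#'
#' @param image_species_map named character vector: names are image ids,
#'   values species.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return Object of class `cv_plan`: `fold` (named integer per image),
#'   `species_fold` (named integer per species), `k`.
#' @export
make_cv_plan <- function(image_species_map, k = 5, seed = 1L) {
  sp <- unique(image_species_map)
  if (length(sp) < k) stop_input("fewer species than folds")
  with_seed(seed, {
    shuffled <- sample(sp)
    species_fold <- stats::setNames(rep(seq_len(k),
                                        length.out = length(sp)),
                                    shuffled)
    fold <- species_fold[image_species_map]
    names(fold) <- names(image_species_map)
    structure(list(fold = fold, species_fold = species_fold, k = k),
              class = "cv_plan")
  })
}

#' Aggregate image scores to species scores
#'
#' The headline species value is the maximum over its images (humans tend
#' to generalize from the most attractive representation); the mean is
#' exported alongside for sensitivity analyses.
#'
#' @param image_scores named numeric vector of per-image scores.
#' @param image_species_map named character vector mapping image ids to
#'   species; every scored image must be mapped.
#' @param mode `"max"` or `"mean"` for the `score` column.
#' @return data.frame `species`, `score`, `score_max`, `score_mean`.
#' @export
species_score <- function(image_scores, image_species_map,
                          mode = c("max", "mean")) {
  mode <- match.arg(mode)
  miss <- setdiff(names(image_scores), names(image_species_map))
  if (length(miss))
    stop_input("unmapped image(s): ", paste(miss, collapse = ", "))
  sp <- image_species_map[names(image_scores)]
  mx <- tapply(image_scores, sp, max)
  mn <- tapply(image_scores, sp, mean)
  data.frame(species = names(mx),
             score = if (mode == "max") as.numeric(mx) else as.numeric(mn),
             score_max = as.numeric(mx), score_mean = as.numeric(mn),
             row.names = NULL, stringsAsFactors = FALSE)
}
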