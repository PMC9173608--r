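#' Per-family summary of species aesthetic scores
#'
#' Recomputes the family-level summaries reported for species score
#' tables: mean, SD and species count per family, sorted by decreasing
#' mean. Supply any species table with `family` and `score` columns
#' (for example a published species/score supplement, or the output of
#' [species_score()] joined to a taxonomy).
#'
#' @param species_table data.frame with columns `family` and `score`.
#' @param min_n drop families with fewer species than this (default 1).
#' @return data.frame `family`, `n`, `mean`, `sd`.
#' @export
family_summary <- function(species_table, min_n = 1) {
  if (!all(c("family", "score") %in% names(species_table)))
    stop_input("need `family` and `score` columns")
  sp <- split(species_table$score, species_table$family)
  out <- data.frame(family = names(sp),
                    n = vapply(sp, length, integer(1)),
                    mean = vapply(sp, mean, numeric(1)),
                    sd = vapply(sp, stats::sd, numeric(1)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[out$n >= min_n, ]
  out[order(-out$mean), ]
}

#' Run the full synthetic pipeline once
#'
#' Desk-scale end-to-end smoke run used by the acceptance report and the
#' examples: generates images, extracts features, designs the survey set,
#' simulates matches, rates them, fits the feature model, and computes
#' the diversity metrics on a simulated tree and trait table.
#'
#' @param n_images number of synthetic fish images.
#' @param n_matches number of simulated pairwise matches.
#' @param n_species number of species in the tree/traits stage.
#' @param canvas_px canvas side for the synthetic images.
#' @param seed integer seed driving every stochastic stage.
#' @return A list with the main stage outputs (features, selection,
#'   rating, feature model, diversity tables).
#' @export
run_pipeline_demo <- function(n_images = 40, n_matches = 4000,
                              n_species = 40, canvas_px = 128, seed = 1L) {
  specs <- with_seed(seed, lapply(seq_len(n_images), function(i)
    fish_spec(body_aspect = stats::runif(1, 1, 3.5),
              n_stripes = sample(0:4, 1),
              palette = lapply(seq_len(sample(1:3, 1)), function(j)
                stats::runif(3)),
              saturation_scale = stats::runif(1, 0.3, 1),
              canvas_px = canvas_px, seed = i)))
  imgs <- lapply(specs, generate_fish_image)
  names(imgs) <- sprintf("img%03d", seq_along(imgs))
  fc <- feature_config(seed = seed)
  feats <- extract_features_batch(imgs, fc)
  fm <- as.matrix(feats[, -1])
  keep_cols <- apply(fm, 2, stats::sd) > 0
  pca <- fit_pca(fm[, keep_cols, drop = FALSE],
                 n_components = min(5, sum(keep_cols)))
  sel <- select_survey_set(pca, n_vertex = min(8, n_images %/% 4),
                           n_fill = min(8, n_images %/% 4), seed = seed)
  latent <- stats::setNames(1500 + 200 * scale(fm[, "mean_saturation"])[, 1],
                            names(imgs))
  matches <- simulate_matches(latent, n_matches, seed = seed)
  rating <- rate_items(matches, rating_config(n_randomizations = 100,
                                              seed = seed))
  melo <- rating_of(rating, names(imgs))
  filt <- suppressWarnings(
    correlation_filter(fm[, keep_cols, drop = FALSE], melo))
  if (length(filt) >= n_images - 2) {  # keep the model identifiable
    ry <- abs(stats::cor(fm[, filt, drop = FALSE], melo))[, 1]
    filt <- names(sort(ry, decreasing = TRUE))[seq_len(n_images %/% 3)]
  }
  model <- fit_feature_model(fm[, filt, drop = FALSE], melo)
  st <- simulate_tree_with_trait(n_species, lambda_true = 1, seed = seed)
  traits <- simulate_trait_table(n_species, seed = seed)
  div <- data.frame(species = st$tree$tip.label,
                    age = species_age(st$tree)[st$tree$tip.label],
                    ed = evolutionary_distinctiveness(st$tree)[st$tree$tip.label],
                    di = gower_distinctiveness(traits)[traits$species],
                    row.names = NULL)
  sig <- pagels_lambda(st$tree, st$trait, n_perm = 99, seed = seed)
  list(features = feats, pca = pca, selection = sel, rating = rating,
       feature_model = model, diversity = div, signal = sig)
}
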