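#' Names of the 17-image-feature battery, in stable column order
#' @return Character vector of length 17.
#' @export
feature_names <- function() {
  c("k_colors", "color_entropy", "mean_centroid_distance",
    "dominant_color_share",
    "patch_count", "pattern_repetition", "boundary_sharpness",
    "patch_area_sd", "boundary_fractal_dim",
    "mean_saturation", "sd_saturation", "mean_lightness", "sd_lightness",
    "elongatedness", "circularity", "convexity", "outline_harmonic_power")
}

# The feature registry: each class is a named plug-in so an alternative
# definition is a config change, not a code change. A plug-in takes
# (img, seg, config) and returns a named numeric vector.
default_feature_registry <- function() {
  list(
    color   = function(img, seg, config) color_features(seg),
    pattern = function(img, seg, config) pattern_features(seg, img, config),
    tone    = function(img, seg, config) tone_features(img),
    shape   = function(img, seg, config) shape_features(img$mask, config)
  )
}

#' Extract the 17-feature battery from a masked image
#'
#' Runs colour segmentation once and evaluates the four feature classes
#' (colour heterogeneity, colour-pattern geometry, tone, outline shape).
#' Background pixels never influence any feature.
#'
#' @param img a [masked_image()].
#' @param config a [feature_config()].
#' @param registry feature-class plug-ins; see
#'   `reefaesth:::default_feature_registry` for the contract.
#' @return Named numeric vector in [feature_names()] order.
#' @export
extract_features <- function(img, config = feature_config(),
                             registry = default_feature_registry()) {
  stopifnot(inherits(img, "masked_image"))
  seg <- segment_colors(img, config)
  out <- unlist(lapply(registry, function(f) f(img, seg, config)))
  names(out) <- sub("^[a-z]+\\.", "", names(out))
  known <- intersect(feature_names(), names(out))
  out[c(known, setdiff(names(out), known))]
}

#' Batch feature extraction to a data frame / CSV
#'
#' @param imgs named list of [masked_image()] objects (names become
#'   `image_id`).
#' @param config a [feature_config()].
#' @param path optional CSV output path (columns `image_id` + features in
#'   stable order).
#' @return A `data.frame`, invisibly written to `path` when given.
#' @export
extract_features_batch <- function(imgs, config = feature_config(),
                                   path = NULL) {
  if (is.null(names(imgs)))
    names(imgs) <- sprintf("img%04d", seq_along(imgs))
  rows <- lapply(imgs, extract_features, config = config)
  out <- cbind(data.frame(image_id = names(imgs), stringsAsFactors = FALSE),
               as.data.frame(do.call(rbind, rows)))
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
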