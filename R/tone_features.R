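#' Perceptual lightness and saturation features
#'
#' Organism pixels are converted to HSV (hexcone model, channels in
#' `[0, 1]`); the V ("value") channel serves as the lightness measure.
#' Standard deviations are population SDs.
#'
#' @param img a [masked_image()].
#' @return Named numeric vector: `mean_saturation`, `sd_saturation`,
#'   `mean_lightness`, `sd_lightness`.
#' @export
tone_features <- function(img) {
  stopifnot(inherits(img, "masked_image"))
  hsv <- rgb_to_hsv_mat(masked_rgb(img))
  c(mean_saturation = mean(hsv[, 2]), sd_saturation = sd_pop(hsv[, 2]),
    mean_lightness = mean(hsv[, 3]), sd_lightness = sd_pop(hsv[, 3]))
}
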