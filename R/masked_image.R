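#' Masked organism image
#'
#' The pipeline's raster container: an RGB image together with a boolean
#' organism mask. Pixels outside the mask are background (conventionally
#' white) and are ignored by every feature computation.
#'
#' @param pixels numeric array `H x W x 3`, RGB in `[0, 1]`.
#' @param mask logical matrix `H x W`; `TRUE` marks organism pixels.
#' @return An object of class `masked_image` (list with `pixels`, `mask`).
#' @examples
#' px <- array(1, dim = c(4, 4, 3))
#' m  <- matrix(FALSE, 4, 4); m[2:3, 2:3] <- TRUE
#' img <- masked_image(px, m)
#' @export
masked_image <- function(pixels, mask) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_input("`pixels` must be an H x W x 3 array")
  if (!is.matrix(mask) || !is.logical(mask))
    stop_input("`mask` must be a logical matrix")
  if (!all(dim(mask) == dim(pixels)[1:2]))
    stop_input("`mask` dimensions must match `pixels`")
  if (!any(mask)) stop_input("mask must contain at least one TRUE pixel")
  if (!all(is.finite(pixels))) stop_input("pixel values must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop_input("pixel values must lie in [0, 1]")
  structure(list(pixels = pixels, mask = mask), class = "masked_image")
}

#' @export
print.masked_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<masked_image %d x %d, %d masked pixels (%.1f%%)>\n",
              d[1], d[2], sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Derive a mask from an (almost) white background
#'
#' Pixels whose three channels all exceed `threshold` are treated as
#' background, mirroring the convention of organism photographs displayed
#' against a white background.
#'
#' @param pixels RGB array in `[0, 1]`.
#' @param threshold per-channel background cutoff (default `250/255`).
#' @return A `masked_image`.
#' @export
auto_mask_white <- function(pixels, threshold = 250 / 255) {
  bg <- pixels[, , 1] > threshold & pixels[, , 2] > threshold &
    pixels[, , 3] > threshold
  masked_image(pixels, !bg)
}

#' Write / read a masked image as a PNG pair
#'
#' The image is written to `path` and the mask (0/255 grayscale) to
#' `paste0(tools::file_path_sans_ext(path), "_mask.png")`; the reader
#' round-trips both.
#'
#' @param img a `masked_image`.
#' @param path PNG file path for the RGB image.
#' @return `write_masked_image` returns `path` invisibly;
#'   `read_masked_image` returns a `masked_image`.
#' @export
write_masked_image <- function(img, path) {
  stopifnot(inherits(img, "masked_image"))
  png::writePNG(img$pixels, path)
  png::writePNG(matrix(as.numeric(img$mask), nrow(img$mask)),
                mask_path_for(path))
  invisible(path)
}

#' @rdname write_masked_image
#' @export
read_masked_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  m <- png::readPNG(mask_path_for(path))
  if (length(dim(m)) == 3L) m <- m[, , 1]
  masked_image(px, m > 0.5)
}

mask_path_for <- function(path) {
  paste0(sub("\\.png$", "", path, ignore.case = TRUE), "_mask.png")
}

# masked pixels as an n x 3 matrix (row-major over the mask index order)
masked_rgb <- function(img) {
  idx <- which(img$mask)
  cbind(img$pixels[, , 1][idx], img$pixels[, , 2][idx], img$pixels[, , 3][idx])
}
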