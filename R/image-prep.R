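#' Read an RGB image into a [0, 1] array
#'
#' Decodes an 8-bit RGB PNG into an `H x W x 3` numeric array on the
#' `[0, 1]` scale (byte values divided by 255). An
#' alpha channel, if present, is dropped. Greyscale input is rejected: the
#' feature pipeline is defined on colour images.
#'
#' @param path Path to the image file.
#' @return Numeric array `H x W x 3` with values in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(sprintf("Image file not found: '%s'.", path))
  px <- tryCatch(png::readPNG(path), error = function(e) {
    abort(sprintf("Cannot decode '%s' as PNG: %s", path, conditionMessage(e)))
  })
  if (length(dim(px)) == 2L) {
    abort(sprintf("'%s' is a greyscale image; an RGB image is required.", path))
  }
  nch <- dim(px)[3]
  if (nch == 4L) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3] != 3L) {
    abort(sprintf("'%s' has %d channels; an RGB image is required.", path, nch))
  }
  px
}

#' Crop the central window of an image
#'
#' Returns the `crop_h x crop_w` window centred in the image, the region used
#' for feature extraction. Coordinates are 0-based half-open windows; with odd
#' margins the extra row/column goes to the bottom/right (floor rule). No
#' resampling is performed.
#'
#' @param image `H x W x 3` array (or `H x W` matrix).
#' @param crop_h,crop_w Window size; must not exceed the image size.
#' @return Array (or matrix) of exactly `crop_h x crop_w` pixels.
#' @export
#' @examples
#' img <- array(runif(64 * 64 * 3), c(64, 64, 3))
#' dim(center_crop(img, 32, 32))
center_crop <- function(image, crop_h, crop_w = crop_h) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (crop_h < 1 || crop_w < 1 || crop_h > h || crop_w > w) {
    abort(sprintf(
      "Crop %d x %d is invalid for a %d x %d image.", crop_h, crop_w, h, w
    ))
  }
  r0 <- (h - crop_h) %/% 2L
  c0 <- (w - crop_w) %/% 2L
  rows <- (r0 + 1L):(r0 + crop_h)
  cols <- (c0 + 1L):(c0 + crop_w)
  if (length(d) == 2L) image[rows, cols, drop = FALSE]
  else image[rows, cols, , drop = FALSE]
}
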