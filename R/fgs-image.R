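#' Construct a 2-D intensity image
#'
#' `fgs_image` is the shared container for all phantom images: a numeric
#' matrix of non-negative digital numbers (DN) together with the sensor bit
#' depth, acquisition provenance, and optional spatial calibration.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities in DN.
#'   Both dimensions must be at least 16 pixels.
#' @param bit_depth Integer sensor bit depth (e.g. 8, 12, 16). All pixel
#'   values must lie in `[0, 2^bit_depth - 1]`.
#' @param source Character provenance string (file path, frame index,
#'   or generator description).
#' @param pixel_pitch_mm Optional positive scalar: millimetres per pixel at
#'   the working distance.
#' @param lossy Logical; `TRUE` when the image went through lossy
#'   compression (JPEG) and quantitative results should disclose it.
#'
#' @return An object of class `fgs_image`: a list with elements `pixels`,
#'   `bit_depth`, `source`, `pixel_pitch_mm`, `lossy`.
#' @export
#' @examples
#' img <- fgs_image(matrix(1000, 32, 32), bit_depth = 16)
#' dim(img$pixels)
fgs_image <- function(pixels, bit_depth = 16L, source = "in-memory",
                      pixel_pitch_mm = NULL, lossy = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (any(dim(pixels) < 16L)) {
    stop("image dimensions must both be >= 16 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels)) || any(pixels < 0)) {
    stop("pixel values must be finite and non-negative", call. = FALSE)
  }
  bit_depth <- as.integer(bit_depth)
  if (length(bit_depth) != 1L || is.na(bit_depth) || bit_depth < 1L ||
      bit_depth > 32L) {
    stop("`bit_depth` must be a single integer in [1, 32]", call. = FALSE)
  }
  full_scale <- 2^bit_depth - 1
  if (max(pixels) > full_scale + 1e-9) {
    stop(sprintf("pixel values exceed 2^%d - 1 = %s", bit_depth,
                 format(full_scale)), call. = FALSE)
  }
  if (!is.null(pixel_pitch_mm)) {
    stopifnot(is.numeric(pixel_pitch_mm), length(pixel_pitch_mm) == 1L,
              pixel_pitch_mm > 0)
  }
  structure(
    list(pixels = pixels, bit_depth = bit_depth, source = as.character(source),
         pixel_pitch_mm = pixel_pitch_mm, lossy = isTRUE(lossy)),
    class = "fgs_image"
  )
}

#' @export
print.fgs_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fgs_image> %d x %d px, %d-bit, range [%g, %g]%s\n",
              d[1], d[2], x$bit_depth, min(x$pixels), max(x$pixels),
              if (x$lossy) ", lossy" else ""))
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Full-scale digital number of an image
#'
#' @param image An [fgs_image].
#' @return `2^bit_depth - 1`.
#' @export
full_scale_dn <- function(image) {
  stopifnot(inherits(image, "fgs_image"))
  2^image$bit_depth - 1
}

is_fgs_image <- function(x) inherits(x, "fgs_image")

assert_image <- function(image) {
  if (!is_fgs_image(image)) stop("expected an `fgs_image`", call. = FALSE)
  invisible(image)
}
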