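#' Grayscale image container
#'
#' A `gray_image` is the common currency of the package: a 2-D grid of real
#' intensities plus bit-depth metadata.  Pixels are stored row-major with a
#' top-left origin and 0-based `(row, col)` coordinates in all documentation;
#' in R the underlying matrix is indexed 1-based as usual, with the matrix row
#' corresponding to image y.
#'
#' @param pixels Numeric matrix of intensities.  All values must be finite.
#' @param bit_depth Integer, one of 8, 16 or 32.
#' @param pixel_spacing Optional numeric pair of positive pixel spacings in mm
#'   (informational only).
#'
#' @return An object of class `gray_image`: a list with elements `pixels`,
#'   `bit_depth` and `pixel_spacing`.
#' @export
#' @examples
#' img <- gray_image(matrix(c(0, 255, 255, 0), 2, 2))
#' dim(img)
gray_image <- function(pixels, bit_depth = 8L, pixel_spacing = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite (no NA/NaN/Inf)", call. = FALSE)
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1 x 1", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L, 32L))
    stop("`bit_depth` must be 8, 16 or 32", call. = FALSE)
  if (!is.null(pixel_spacing)) {
    pixel_spacing <- as.numeric(pixel_spacing)
    if (length(pixel_spacing) != 2L || any(!is.finite(pixel_spacing)) ||
        any(pixel_spacing <= 0))
      stop("`pixel_spacing` must be two positive reals (mm)", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 pixel_spacing = pixel_spacing),
            class = "gray_image")
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<gray_image> %d x %d, bit depth %d, range [%.4g, %.4g]\n",
              d[1], d[2], x$bit_depth, min(x$pixels), max(x$pixels)))
  if (!is.null(x$pixel_spacing))
    cat(sprintf("  pixel spacing: %g x %g mm\n",
                x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

#' Test for gray_image
#' @param x Object.
#' @return `TRUE` if `x` is a `gray_image`.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' Coerce to gray_image
#'
#' Matrices are wrapped with the given bit depth; existing `gray_image`
#' objects are returned unchanged.
#'
#' @param x Matrix or `gray_image`.
#' @param bit_depth Bit depth used when wrapping a bare matrix.
#' @return A `gray_image`.
#' @export
as_gray_image <- function(x, bit_depth = 8L) {
  if (is_gray_image(x)) return(x)
  gray_image(x, bit_depth = bit_depth)
}

#' Round intensities to the integer grid of the image's bit depth
#'
#' Values are rounded half away from the floor to the nearest integer and
#' clipped to `[0, 2^bit_depth - 1]`.
#'
#' @param img A `gray_image`.
#' @return A `gray_image` with integer intensities.
#' @export
quantize <- function(img) {
  img <- as_gray_image(img)
  top <- 2^img$bit_depth - 1
  px <- pmin(pmax(round(img$pixels), 0), top)
  gray_image(px, bit_depth = img$bit_depth, pixel_spacing = img$pixel_spacing)
}

#' Rescale an image affinely onto the 8-bit range [0, 255]
#'
#' All metric and denoising computation in this package runs on the 255
#' scale, whatever the acquisition depth, because the quality metrics are
#' defined against the 8-bit peak 255.  A constant image maps to all zeros
#' (there is no contrast to place).  The map is idempotent on images already
#' spanning `[0, 255]`.
#'
#' @param img A `gray_image`.
#' @return A `gray_image` on `[0, 255]` with `bit_depth = 8`.
#' @export
#' @examples
#' to_unit_range(gray_image(matrix(c(10, 20, 30, 10), 2, 2)))$pixels
to_unit_range <- function(img) {
  img <- as_gray_image(img)
  lo <- min(img$pixels); hi <- max(img$pixels)
  px <- if (hi > lo) (img$pixels - lo) / (hi - lo) * 255 else
    matrix(0, nrow(img$pixels), ncol(img$pixels))
  gray_image(px, bit_depth = 8L, pixel_spacing = img$pixel_spacing)
}

# internal: clip a numeric matrix to [0, 255]
clip255 <- function(px) pmin(pmax(px, 0), 255)

# internal: pull the pixel matrix from gray_image or matrix input
pixel_matrix <- function(x) {
  if (is_gray_image(x)) x$pixels
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a gray_image or numeric matrix", call. = FALSE)
}

# internal: check two images share dimensions
check_same_dim <- function(a, b, what = "images") {
  if (!identical(dim(pixel_matrix(a)), dim(pixel_matrix(b))))
    stop(sprintf("%s must share dimensions", what), call. = FALSE)
  invisible(TRUE)
}
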