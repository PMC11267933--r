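#' Specify a synthetic anatomical phantom
#'
#' Phantoms are deterministic piecewise-smooth test images on `[0, 255]`
#' standing in for clinical CT/MR acquisitions: homogeneous regions,
#' ellipsoidal organs and thin ridges, the features medical denoisers must
#' preserve.
#'
#' @param kind `"ridge"` (dark Y-shaped airway ridge on bright lung-like
#'   ellipses, a thoracic carina analog), `"ellipses"` (nested ellipses of
#'   distinct intensities, a ventricle analog), `"checker"` or `"uniform"`.
#' @param size Integer pair `(m, n)`, both at least 8.  The default
#'   256 x 256 keeps experiments fast; use `c(340, 480)` to mirror a typical
#'   480 x 340 (width x height) clinical acquisition.
#' @param contrast Peak intensity in `(0, 255]`.
#' @param seed Integer seed (kept for interface uniformity; phantom
#'   construction is deterministic).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(kind = c("ellipses", "ridge", "checker", "uniform"),
                         size = c(256L, 256L), contrast = 200, seed = 1L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 8L))
    stop("`size` must be two integers, both >= 8", call. = FALSE)
  if (!is.finite(contrast) || contrast <= 0 || contrast > 255)
    stop("`contrast` must lie in (0, 255]", call. = FALSE)
  structure(list(kind = kind, size = size, contrast = contrast,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic phantom image
#'
#' Identical specs give identical images.  The result carries a `regions`
#' attribute: an integer matrix labelling the piecewise-constant regions
#' (useful as ground truth for edge masks and region statistics).
#'
#' @param spec A [phantom_spec].
#' @return A [gray_image] on `[0, 255]` with a `regions` attribute.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("checker", size = c(8, 8), contrast = 255))
#' ph$pixels[1:2, 1:2]
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- spec$size[1]; n <- spec$size[2]; a <- spec$contrast
  yy <- matrix(seq_len(m), m, n)
  xx <- matrix(seq_len(n), m, n, byrow = TRUE)
  cy <- (m + 1) / 2; cx <- (n + 1) / 2
  in_ellipse <- function(y0, x0, ry, rx)
    ((yy - y0) / ry)^2 + ((xx - x0) / rx)^2 <= 1
  regions <- matrix(0L, m, n)
  px <- switch(spec$kind,
    uniform = matrix(a, m, n),
    checker = {
      regions <- (yy + xx) %% 2L
      matrix(ifelse(regions == 1L, a, 0), m, n)
    },
    ellipses = {
      lev <- a * c(0.15, 1, 0.6, 0.35)   # background, outer, middle, inner
      e1 <- in_ellipse(cy, cx, 0.42 * m, 0.34 * n)
      e2 <- in_ellipse(cy, cx, 0.28 * m, 0.20 * n)
      e3 <- in_ellipse(0.8 * cy, cx, 0.10 * m, 0.08 * n)
      regions[e1] <- 1L; regions[e2] <- 2L; regions[e3] <- 3L
      matrix(lev[regions + 1L], m, n)
    },
    ridge = {
      lungL <- in_ellipse(cy, 0.30 * n, 0.38 * m, 0.22 * n)
      lungR <- in_ellipse(cy, 0.70 * n, 0.38 * m, 0.22 * n)
      # Y-shaped airway: a vertical trachea branching into two bronchi
      w <- max(1, round(0.015 * n))
      stem <- abs(xx - cx) <= w & yy <= 0.45 * m
      brL <- abs((xx - cx) + (yy - 0.45 * m) * 0.7) <= w &
        yy > 0.45 * m & yy <= 0.75 * m
      brR <- abs((xx - cx) - (yy - 0.45 * m) * 0.7) <= w &
        yy > 0.45 * m & yy <= 0.75 * m
      regions[lungL | lungR] <- 1L
      regions[stem | brL | brR] <- 2L
      lev <- c(0.45 * a, a, 0.1 * a)     # mediastinum, lungs, airway
      matrix(lev[regions + 1L], m, n)
    })
  img <- gray_image(px, bit_depth = 8L)
  attr(img, "regions") <- regions
  img
}
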