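#' Specify a noise process
#'
#' Three processes cover the dominant noise of the targeted modalities:
#' Poisson-statistics quantum mottle in CT, additive two-component Gaussian
#' noise in MRI, and Rayleigh-distributed background noise in magnitude MR
#' images.
#'
#' @param kind One of `"quantum_mottle"`, `"gaussian"`, `"rayleigh"`.
#' @param p_avg Mean photon count per pixel at full intensity (quantum
#'   mottle); must be positive.
#' @param d_rs Nonnegative scale factor multiplying the first Gaussian
#'   component's variance (its square root multiplies the draw).
#' @param sigma1,sigma2 Standard deviations (grey levels) of the two
#'   independent zero-mean Gaussian components.
#' @param g0 Minimum grey level of the Rayleigh density.
#' @param g1 Positive scale of the Rayleigh density
#'   `(2/g1) (g - g0) exp(-(g - g0)^2 / g1)`.
#' @param seed Integer seed; every sampler reproduces bit-identically under
#'   a fixed seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(kind = c("quantum_mottle", "gaussian", "rayleigh"),
                       p_avg = 1000, d_rs = 1, sigma1 = 3, sigma2 = 4,
                       g0 = 0, g1 = 50, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "quantum_mottle" && (!is.finite(p_avg) || p_avg <= 0))
    stop("`p_avg` must be positive", call. = FALSE)
  if (kind == "gaussian" && (d_rs < 0 || sigma1 < 0 || sigma2 < 0))
    stop("`d_rs`, `sigma1`, `sigma2` must be nonnegative", call. = FALSE)
  if (kind == "rayleigh" && (!is.finite(g1) || g1 <= 0))
    stop("`g1` must be positive", call. = FALSE)
  structure(list(kind = kind, p_avg = p_avg, d_rs = d_rs, sigma1 = sigma1,
                 sigma2 = sigma2, g0 = g0, g1 = g1, seed = as.integer(seed)),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  pars <- switch(x$kind,
                 quantum_mottle = sprintf("p_avg=%g", x$p_avg),
                 gaussian = sprintf("d_rs=%g, sigma1=%g, sigma2=%g",
                                    x$d_rs, x$sigma1, x$sigma2),
                 rayleigh = sprintf("g0=%g, g1=%g", x$g0, x$g1))
  cat(sprintf("<noise_spec> %s (%s), seed %d\n", x$kind, pars, x$seed))
  invisible(x)
}

#' Relative quantum mottle level
#'
#' The observed mottle level for a mean photon count `P` per pixel, with the
#' photon-count standard deviation `sqrt(P)`: `sqrt(sqrt(P)) / P`, i.e.
#' `P^(-3/4)`.  This is the level formula as used by the imaging literature
#' this package follows; the pixel-level mottle injector
#' ([add_quantum_mottle]) is the Poisson process itself, exposed separately.
#'
#' @param p_avg Positive mean photon count per pixel.
#' @return Nonnegative mottle level.
#' @export
#' @examples
#' quantum_mottle_level(16)   # 0.125
quantum_mottle_level <- function(p_avg) {
  if (any(!is.finite(p_avg)) || any(p_avg <= 0))
    stop("`p_avg` must be positive", call. = FALSE)
  sqrt(sqrt(p_avg)) / p_avg
}

#' Corrupt an image with quantum mottle (Poisson photon noise)
#'
#' Each pixel value `v` on the 255 scale is mapped to an expected photon
#' count `lambda = v * p_avg / 255` (so a full-intensity pixel has about
#' `p_avg` photons), a Poisson draw is taken, and the count is scaled back by
#' `255 / p_avg`.  Output is clipped to `[0, 255]`.
#'
#' @param img A [gray_image] on the 255 scale.
#' @param spec A [noise_spec] of kind `"quantum_mottle"`.
#' @return A noisy [gray_image].
#' @export
add_quantum_mottle <- function(img, spec) {
  img <- as_gray_image(img)
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$kind != "quantum_mottle")
    stop("`spec` must have kind 'quantum_mottle'", call. = FALSE)
  if (!is.finite(spec$p_avg) || spec$p_avg <= 0)
    stop("`p_avg` must be positive", call. = FALSE)
  lambda <- img$pixels * spec$p_avg / 255
  counts <- withr::with_seed(spec$seed,
                             stats::rpois(length(lambda), as.vector(lambda)))
  px <- matrix(counts * 255 / spec$p_avg, nrow(lambda), ncol(lambda))
  gray_image(clip255(px), bit_depth = img$bit_depth,
             pixel_spacing = img$pixel_spacing)
}

#' Corrupt an image with two-component additive Gaussian noise
#'
#' Per-pixel noise `N = sqrt(d_rs) * N1 + N2` with independent zero-mean
#' components `N1 ~ Normal(0, sigma1^2)` and `N2 ~ Normal(0, sigma2^2)`,
#' added to the image and clipped to `[0, 255]`.
#'
#' @param img A [gray_image].
#' @param spec A [noise_spec] of kind `"gaussian"`.
#' @return A noisy [gray_image].
#' @export
add_gaussian <- function(img, spec) {
  img <- as_gray_image(img)
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$kind != "gaussian")
    stop("`spec` must have kind 'gaussian'", call. = FALSE)
  if (spec$d_rs < 0 || spec$sigma1 < 0 || spec$sigma2 < 0)
    stop("`d_rs`, `sigma1`, `sigma2` must be nonnegative", call. = FALSE)
  npix <- length(img$pixels)
  noise <- withr::with_seed(spec$seed, {
    n1 <- stats::rnorm(npix, 0, spec$sigma1)
    n2 <- stats::rnorm(npix, 0, spec$sigma2)
    sqrt(spec$d_rs) * n1 + n2
  })
  px <- img$pixels + matrix(noise, nrow(img$pixels), ncol(img$pixels))
  gray_image(clip255(px), bit_depth = img$bit_depth,
             pixel_spacing = img$pixel_spacing)
}

#' Draw Rayleigh-distributed noise values
#'
#' Samples from the density `(2/g1) (g - g0) exp(-(g - g0)^2 / g1)` for
#' `g >= g0` (a Rayleigh distribution with scale `sigma = sqrt(g1/2)`
#' shifted by `g0`), by inversion of the closed-form CDF
#' `1 - exp(-(g - g0)^2 / g1)`.
#'
#' @param n Number of draws.
#' @param g0 Minimum grey level.
#' @param g1 Positive scale.
#' @return Numeric vector of draws, all `>= g0`.
#' @export
rrayleigh_noise <- function(n, g0 = 0, g1 = 50) {
  if (!is.finite(g1) || g1 <= 0) stop("`g1` must be positive", call. = FALSE)
  g0 + sqrt(-g1 * log(stats::runif(n)))
}

#' Add Rayleigh background noise to an image
#'
#' Rayleigh noise concentrates in the background of magnitude MR images, so
#' by default draws are added only on pixels darker than 10 grey levels; an
#' explicit logical `background_mask` overrides this (use a full `TRUE` mask
#' for whole-image noise).  Output is clipped to `[0, 255]`.
#'
#' @param img A [gray_image].
#' @param spec A [noise_spec] of kind `"rayleigh"`.
#' @param background_mask Optional logical matrix matching the image
#'   dimensions.
#' @return A noisy [gray_image].
#' @export
add_rayleigh_background <- function(img, spec, background_mask = NULL) {
  img <- as_gray_image(img)
  stopifnot(inherits(spec, "noise_spec"))
  if (spec$kind != "rayleigh")
    stop("`spec` must have kind 'rayleigh'", call. = FALSE)
  if (!is.finite(spec$g1) || spec$g1 <= 0)
    stop("`g1` must be positive", call. = FALSE)
  px <- img$pixels
  if (is.null(background_mask)) {
    background_mask <- px < 10
  } else {
    if (!is.logical(background_mask) ||
        !identical(dim(background_mask), dim(px)))
      stop("`background_mask` must be a logical matrix matching the image dimensions",
           call. = FALSE)
  }
  idx <- which(background_mask)
  if (length(idx)) {
    draws <- withr::with_seed(spec$seed,
                              rrayleigh_noise(length(idx), spec$g0, spec$g1))
    px[idx] <- px[idx] + draws
  }
  gray_image(clip255(px), bit_depth = img$bit_depth,
             pixel_spacing = img$pixel_spacing)
}

#' Apply a noise spec to an image
#'
#' Dispatches to the sampler matching `spec$kind`.
#'
#' @param img A [gray_image].
#' @param spec A [noise_spec].
#' @return A noisy [gray_image].
#' @export
add_noise <- function(img, spec) {
  stopifnot(inherits(spec, "noise_spec"))
  switch(spec$kind,
         quantum_mottle = add_quantum_mottle(img, spec),
         gaussian = add_gaussian(img, spec),
         rayleigh = add_rayleigh_background(img, spec))
}
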