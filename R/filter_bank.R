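#' Specify a comparison filter
#'
#' The bank covers the eleven classical denoisers the CTD method is
#' benchmarked against: Gaussian and Wiener smoothing, two Laplacian
#' variants, the plain spatial operators (average, minimum, median),
#' Perona-Malik anisotropic diffusion (PMAD), the Kuan and Frost adaptive
#' speckle filters, and Haar wavelet shrinkage.
#'
#' @param name One of `"gaussian"`, `"wiener"`, `"laplacian"`,
#'   `"laplacian_sharp"`, `"average"`, `"minimum"`, `"median"`, `"pmad"`,
#'   `"kuan"`, `"frost"`, `"haar_wavelet"`.
#' @param params Named list overriding the filter's default parameters
#'   (window sizes must be odd positive integers; iteration counts
#'   nonnegative).
#' @return A `filter_spec` object with all parameters resolved.
#' @export
filter_spec <- function(name, params = list()) {
  defaults <- filter_defaults()
  if (!name %in% names(defaults))
    stop(sprintf("unknown filter '%s'; valid names: %s", name,
                 paste(names(defaults), collapse = ", ")), call. = FALSE)
  p <- utils::modifyList(defaults[[name]], as.list(params))
  for (key in intersect(names(p), c("window", "size"))) {
    w <- p[[key]]
    if (!is.numeric(w) || w != as.integer(w) || w < 1 || w %% 2 == 0)
      stop(sprintf("filter '%s': `%s` must be an odd positive integer",
                   name, key), call. = FALSE)
  }
  if (!is.null(p$iterations) && p$iterations < 0)
    stop(sprintf("filter '%s': `iterations` must be >= 0", name),
         call. = FALSE)
  structure(list(name = name, params = p), class = "filter_spec")
}

filter_defaults <- function() {
  list(
    gaussian        = list(sigma = 1),
    wiener          = list(window = 3L),
    laplacian       = list(),
    laplacian_sharp = list(),
    average         = list(window = 7L),
    minimum         = list(window = 3L),
    median          = list(window = 3L),
    pmad            = list(iterations = 15L, kappa = 30, lambda = 0.15),
    kuan            = list(window = 3L),
    frost           = list(window = 3L, damping = 1),
    haar_wavelet    = list(levels = 2L)
  )
}

#' The default comparison filter bank
#'
#' @return List of the eleven [filter_spec]s with their default
#'   parameterizations, in bank order.
#' @export
list_filters <- function() {
  lapply(names(filter_defaults()), filter_spec)
}

#' @export
print.filter_spec <- function(x, ...) {
  pars <- if (length(x$params))
    paste(names(x$params), unlist(lapply(x$params, format)),
          sep = "=", collapse = ", ") else "no parameters"
  cat(sprintf("<filter_spec> %s (%s)\n", x$name, pars))
  invisible(x)
}

#' Apply a comparison filter
#'
#' All filters use replicate boundary handling.  The two Laplacian variants
#' return signed edge/sharpening maps (not clipped); every other filter maps
#' `[0, 255]` into `[0, 255]`.
#'
#' @param img A [gray_image].
#' @param spec A [filter_spec], or a filter name (defaults then apply).
#' @return The filtered [gray_image].
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("ellipses", size = c(32, 32)))
#' apply_filter(ph, filter_spec("median"))
apply_filter <- function(img, spec) {
  img <- as_gray_image(img)
  if (is.character(spec)) spec <- filter_spec(spec)
  stopifnot(inherits(spec, "filter_spec"))
  u <- img$pixels
  p <- spec$params
  out <- switch(spec$name,
    gaussian        = conv2_replicate(u, gaussian_kernel(p$sigma)),
    wiener          = wiener_filter(u, p$window),
    laplacian       = conv2_replicate(u, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0),
                                                3, 3)),
    laplacian_sharp = u - conv2_replicate(u, matrix(c(1, 1, 1, 1, -8, 1,
                                                      1, 1, 1), 3, 3)),
    average         = conv2_replicate(u, matrix(1 / p$window^2,
                                                p$window, p$window)),
    minimum         = window_reduce(u, p$window, "min"),
    median          = window_reduce(u, p$window, "median"),
    pmad            = pmad_filter(u, p$iterations, p$kappa, p$lambda),
    kuan            = kuan_filter(u, p$window),
    frost           = frost_filter(u, p$window, p$damping),
    haar_wavelet    = haar_shrink(u, p$levels))
  gray_image(out, bit_depth = img$bit_depth,
             pixel_spacing = img$pixel_spacing)
}

## ---- shared neighbourhood machinery ------------------------------------

# replicate-pad a matrix by k rows/cols on every side
pad_replicate <- function(u, k) {
  if (k == 0) return(u)
  ri <- c(rep(1L, k), seq_len(nrow(u)), rep(nrow(u), k))
  ci <- c(rep(1L, k), seq_len(ncol(u)), rep(ncol(u), k))
  u[ri, ci, drop = FALSE]
}

# 2-D correlation with replicate boundary; kernel must have odd dimensions
conv2_replicate <- function(u, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  stopifnot(kr %% 2 == 1, kc %% 2 == 1)
  k <- max((kr - 1L) %/% 2L, (kc - 1L) %/% 2L)
  up <- pad_replicate(u, k)
  m <- nrow(u); n <- ncol(u)
  out <- matrix(0, m, n)
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    w <- kernel[i, j]
    if (w == 0) next
    di <- i - (kr + 1L) %/% 2L; dj <- j - (kc + 1L) %/% 2L
    out <- out + w * up[(k + di + 1L):(k + di + m),
                        (k + dj + 1L):(k + dj + n), drop = FALSE]
  }
  out
}

# stack of the w*w shifted copies of u (replicate boundary), as a matrix
# with one row per pixel and one column per window offset
window_stack <- function(u, w) {
  k <- (w - 1L) %/% 2L
  up <- pad_replicate(u, k)
  m <- nrow(u); n <- ncol(u)
  cols <- vector("list", w * w)
  idx <- 1L
  for (dj in -k:k) for (di in -k:k) {
    cols[[idx]] <- as.vector(up[(k + di + 1L):(k + di + m),
                                (k + dj + 1L):(k + dj + n), drop = FALSE])
    idx <- idx + 1L
  }
  do.call(cbind, cols)
}

window_reduce <- function(u, w, stat = c("min", "median")) {
  stat <- match.arg(stat)
  st <- window_stack(u, w)
  v <- switch(stat,
              min = do.call(pmin, as.data.frame(st)),
              median = apply(st, 1L, stats::median))
  matrix(v, nrow(u), ncol(u))
}

# local mean and (population) variance over a w x w window
local_moments <- function(u, w) {
  box <- matrix(1 / w^2, w, w)
  mu <- conv2_replicate(u, box)
  vr <- conv2_replicate(u^2, box) - mu^2
  list(mean = mu, var = pmax(vr, 0))
}

gaussian_kernel <- function(sigma) {
  k <- max(1L, ceiling(3 * sigma))
  x <- (-k):k
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  outer(g, g)
}

## ---- individual filters -------------------------------------------------

# local adaptive Wiener (the classic wiener2 estimator): noise variance
# taken as the mean of the local variances
wiener_filter <- function(u, w) {
  lm <- local_moments(u, w)
  nv <- mean(lm$var)
  gain <- ifelse(lm$var > nv, (lm$var - nv) / lm$var, 0)
  lm$mean + gain * (u - lm$mean)
}

# Perona-Malik anisotropic diffusion, exponential conductance
pmad_filter <- function(u, iterations, kappa, lambda) {
  m <- nrow(u); n <- ncol(u)
  for (it in seq_len(iterations)) {
    dN <- rbind(u[1, , drop = FALSE], u[-m, , drop = FALSE]) - u
    dS <- rbind(u[-1, , drop = FALSE], u[m, , drop = FALSE]) - u
    dW <- cbind(u[, 1, drop = FALSE], u[, -n, drop = FALSE]) - u
    dE <- cbind(u[, -1, drop = FALSE], u[, n, drop = FALSE]) - u
    cN <- exp(-(dN / kappa)^2); cS <- exp(-(dS / kappa)^2)
    cW <- exp(-(dW / kappa)^2); cE <- exp(-(dE / kappa)^2)
    u <- u + lambda * (cN * dN + cS * dS + cW * dW + cE * dE)
  }
  u
}

# Kuan adaptive speckle filter; the noise variation coefficient is estimated
# from the image as the ratio of the mean local variance to the mean squared
# local mean
kuan_filter <- function(u, w) {
  lm <- local_moments(u, w)
  msq <- pmax(lm$mean^2, .Machine$double.eps)
  cu2 <- mean(lm$var) / max(mean(lm$mean^2), .Machine$double.eps)
  ci2 <- lm$var / msq
  gain <- pmax(0, 1 - cu2 / pmax(ci2, .Machine$double.eps)) / (1 + cu2)
  lm$mean + gain * (u - lm$mean)
}

# Frost exponentially-damped convolution filter
frost_filter <- function(u, w, damping) {
  lm <- local_moments(u, w)
  msq <- pmax(lm$mean^2, .Machine$double.eps)
  kfac <- damping * lm$var / msq
  k <- (w - 1L) %/% 2L
  st <- window_stack(u, w)
  dist <- as.vector(sqrt(outer((-k:k)^2, (-k:k)^2, "+")))
  # weights depend on the centre pixel's local statistics and the offset
  num <- 0; den <- 0
  kv <- as.vector(kfac)
  for (j in seq_along(dist)) {
    wt <- exp(-kv * dist[j])
    num <- num + wt * st[, j]
    den <- den + wt
  }
  matrix(num / den, nrow(u), ncol(u))
}

## ---- Haar wavelet shrinkage --------------------------------------------
## Orthonormal separable 2-D Haar pyramid.  Odd extents are replicate-padded
## to even before each level and cropped on synthesis, so round-trip is
## exact for any image size.

haar2_forward <- function(u, levels) {
  if (levels == 0L || nrow(u) < 2L || ncol(u) < 2L) return(list(leaf = u))
  om <- nrow(u); on <- ncol(u)
  if (om %% 2 == 1) u <- rbind(u, u[om, , drop = FALSE])
  if (on %% 2 == 1) u <- cbind(u, u[, on, drop = FALSE])
  io <- seq(1, nrow(u), 2); ie <- io + 1L
  jo <- seq(1, ncol(u), 2); je <- jo + 1L
  lo <- (u[io, , drop = FALSE] + u[ie, , drop = FALSE]) / sqrt(2)
  hi <- (u[io, , drop = FALSE] - u[ie, , drop = FALSE]) / sqrt(2)
  A <- (lo[, jo, drop = FALSE] + lo[, je, drop = FALSE]) / sqrt(2)
  V <- (lo[, jo, drop = FALSE] - lo[, je, drop = FALSE]) / sqrt(2)
  H <- (hi[, jo, drop = FALSE] + hi[, je, drop = FALSE]) / sqrt(2)
  D <- (hi[, jo, drop = FALSE] - hi[, je, drop = FALSE]) / sqrt(2)
  list(orig = c(om, on), A = haar2_forward(A, levels - 1L),
       H = H, V = V, D = D)
}

haar2_inverse <- function(fw) {
  if (!is.null(fw$leaf)) return(fw$leaf)
  A <- haar2_inverse(fw$A)
  half_m <- nrow(A); half_n <- ncol(A)
  lo <- matrix(0, half_m, 2L * half_n)
  hi <- matrix(0, half_m, 2L * half_n)
  jo <- seq(1, 2L * half_n, 2); je <- jo + 1L
  lo[, jo] <- (A + fw$V) / sqrt(2); lo[, je] <- (A - fw$V) / sqrt(2)
  hi[, jo] <- (fw$H + fw$D) / sqrt(2); hi[, je] <- (fw$H - fw$D) / sqrt(2)
  u <- matrix(0, 2L * half_m, 2L * half_n)
  io <- seq(1, 2L * half_m, 2); ie <- io + 1L
  u[io, ] <- (lo + hi) / sqrt(2); u[ie, ] <- (lo - hi) / sqrt(2)
  u[seq_len(fw$orig[1]), seq_len(fw$orig[2]), drop = FALSE]
}

haar2_map_details <- function(fw, f) {
  if (!is.null(fw$leaf)) return(fw)
  fw$H <- f(fw$H); fw$V <- f(fw$V); fw$D <- f(fw$D)
  fw$A <- haar2_map_details(fw$A, f)
  fw
}

# VisuShrink soft thresholding on all detail bands: universal threshold
# sigma_hat * sqrt(2 log(mn)), sigma_hat from the MAD of the finest diagonal
haar_shrink <- function(u, levels) {
  m <- nrow(u); n <- ncol(u)
  if (m < 2^levels || n < 2^levels)
    stop(sprintf("image too small for a %d-level Haar transform", levels),
         call. = FALSE)
  fw <- haar2_forward(u, as.integer(levels))
  hh <- fw$D   # finest diagonal band
  sigma_hat <- stats::median(abs(hh - stats::median(hh))) / 0.6745
  thr <- sigma_hat * sqrt(2 * log(m * n))
  fw <- haar2_map_details(fw, function(d) sign(d) * pmax(abs(d) - thr, 0))
  haar2_inverse(fw)
}
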