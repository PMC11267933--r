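#' Error metrics between an original and a filtered image
#'
#' The six pixelwise error measures, computed exactly as defined for
#' `m x n` images `I` (original) and `I_F` (filtered):
#' `AD = mean(I - I_F)`; `MSE = mean((I - I_F)^2)`; `RMSE = sqrt(MSE)`;
#' `MD = max |I - I_F|`; `NAE = sum|I - I_F| / sum|I|`;
#' `NMSE = sum (I - I_F)^2 / sum I^2`.
#'
#' @param orig,filt Images ([gray_image] or matrix) of equal dimensions.
#' @return Named list with `ad`, `mse`, `rmse`, `md`, `nae`, `nmse`
#'   (the last two are `NA` with a `flags` attribute if `orig` is all
#'   zero).
#' @export
#' @examples
#' error_metrics(matrix(c(10, 20), 1), matrix(c(13, 24), 1))
error_metrics <- function(orig, filt) {
  o <- pixel_matrix(orig); f <- pixel_matrix(filt)
  check_same_dim(o, f)
  d <- o - f
  mse <- mean(d^2)
  out <- list(ad = mean(d), mse = mse, rmse = sqrt(mse), md = max(abs(d)),
              nae = NA_real_, nmse = NA_real_)
  so <- sum(abs(o)); so2 <- sum(o^2)
  flags <- character(0)
  if (so > 0) out$nae <- sum(abs(d)) / so else flags <- c(flags, "nae")
  if (so2 > 0) out$nmse <- sum(d^2) / so2 else flags <- c(flags, "nmse")
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Peak signal-to-noise ratio (dB), 8-bit peak
#'
#' `PSNR = 10 log10(255^2 / MSE)`; identical images (MSE 0) give `Inf`.
#'
#' @inheritParams error_metrics
#' @return PSNR in decibels (possibly `Inf`).
#' @export
psnr <- function(orig, filt) {
  mse <- error_metrics(orig, filt)$mse
  if (mse == 0) Inf else 10 * log10(255^2 / mse)
}

#' Similarity metrics between an original and a filtered image
#'
#' Global (single-window) similarity measures: structural content
#' `SC = sum I^2 / sum I_F^2`; Pearson correlation `CC`; normalized cross
#' correlation `NCC = sum(I * I_F) / sum I^2`; image quality index
#' `IQI = 4 s_of mu_o mu_f / ((s_o^2 + s_f^2)(mu_o^2 + mu_f^2))`; and the
#' global `SSIM = (2 mu_o mu_f + c1)(2 s_of + c2) /
#' ((mu_o^2 + mu_f^2 + c1)(s_o^2 + s_f^2 + c2))` with the standard
#' stabilizers `c1 = (0.01 * 255)^2`, `c2 = (0.03 * 255)^2`.  Moments are
#' population moments (denominator `mn`).
#'
#' @inheritParams error_metrics
#' @return Named list with `sc`, `cc`, `ncc`, `iqi`, `ssim`; degenerate
#'   denominators yield `NA` entries recorded in a `flags` attribute.
#' @export
similarity_metrics <- function(orig, filt) {
  o <- as.vector(pixel_matrix(orig)); f <- as.vector(pixel_matrix(filt))
  check_same_dim(orig, filt)
  mu_o <- mean(o); mu_f <- mean(f)
  var_o <- mean((o - mu_o)^2); var_f <- mean((f - mu_f)^2)
  cov_of <- mean((o - mu_o) * (f - mu_f))
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  out <- list(sc = NA_real_, cc = NA_real_, ncc = NA_real_, iqi = NA_real_,
              ssim = NA_real_)
  flags <- character(0)
  if (sum(f^2) > 0) out$sc <- sum(o^2) / sum(f^2) else flags <- c(flags, "sc")
  if (var_o > 0 && var_f > 0) out$cc <- cov_of / sqrt(var_o * var_f)
  else flags <- c(flags, "cc")
  if (sum(o^2) > 0) out$ncc <- sum(o * f) / sum(o^2)
  else flags <- c(flags, "ncc")
  iqi_den <- (var_o + var_f) * (mu_o^2 + mu_f^2)
  if (iqi_den > 0) out$iqi <- 4 * cov_of * mu_o * mu_f / iqi_den
  else flags <- c(flags, "iqi")
  out$ssim <- (2 * mu_o * mu_f + c1) * (2 * cov_of + c2) /
    ((mu_o^2 + mu_f^2 + c1) * (var_o + var_f + c2))
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Noise and contrast metrics of a filtered image
#'
#' `CNR = |mu_o - mu_f| / sqrt(s_o^2 + s_f^2)` over whole images by
#' default; when both `roi_a` and `roi_b` are given it contrasts the two
#' regions of interest of the filtered image.  `NI = s_f / mu_f` (noise
#' index) and its reciprocal `ASNR = mu_f / s_f`; `IV` is the population
#' variance of the filtered image; `NSD = sqrt(mean((I_F - I_Fn)^2))` is
#' the RMS deviation from the noise-free reference `I_Fn`, and
#' `ENL = mean(I_Fn)^2 / NSD^2`.  When no clean reference is available,
#' `I_Fn` defaults to a 7 x 7 average-smoothed copy of the filtered image
#' (recorded in `fn_reference`).
#'
#' @inheritParams error_metrics
#' @param roi_a,roi_b Optional logical matrices selecting two regions of
#'   interest for CNR.
#' @param fn Optional noise-free reference image for NSD/ENL.
#' @return Named list with `cnr`, `ni`, `asnr`, `iv`, `nsd`, `enl` and
#'   `fn_reference`; degenerate denominators yield `NA` entries recorded in
#'   a `flags` attribute.
#' @export
noise_metrics <- function(orig, filt, roi_a = NULL, roi_b = NULL, fn = NULL) {
  o <- pixel_matrix(orig); f <- pixel_matrix(filt)
  check_same_dim(o, f)
  pvar <- function(x) mean((x - mean(x))^2)
  flags <- character(0)
  out <- list(cnr = NA_real_, ni = NA_real_, asnr = NA_real_,
              iv = NA_real_, nsd = NA_real_, enl = NA_real_,
              fn_reference = NA_character_)
  if (!is.null(roi_a) && !is.null(roi_b)) {
    stopifnot(is.logical(roi_a), is.logical(roi_b),
              identical(dim(roi_a), dim(f)), identical(dim(roi_b), dim(f)))
    a <- f[roi_a]; b <- f[roi_b]
    den <- sqrt(pvar(a) + pvar(b))
    if (den > 0) out$cnr <- abs(mean(a) - mean(b)) / den
    else flags <- c(flags, "cnr")
  } else {
    den <- sqrt(pvar(o) + pvar(f))
    if (den > 0) out$cnr <- abs(mean(o) - mean(f)) / den
    else flags <- c(flags, "cnr")
  }
  mu_f <- mean(f); sd_f <- sqrt(pvar(f))
  if (mu_f != 0) out$ni <- sd_f / mu_f else flags <- c(flags, "ni")
  if (sd_f > 0) out$asnr <- mu_f / sd_f else flags <- c(flags, "asnr")
  out$iv <- pvar(f)
  if (is.null(fn)) {
    fn_px <- conv2_replicate(f, matrix(1 / 49, 7, 7))
    out$fn_reference <- "7x7 average-smoothed filtered image (no clean reference supplied)"
  } else {
    fn_px <- pixel_matrix(fn)
    check_same_dim(f, fn_px)
    out$fn_reference <- "noise-free reference image"
  }
  out$nsd <- sqrt(mean((f - fn_px)^2))
  if (out$nsd > 0) out$enl <- mean(fn_px)^2 / out$nsd^2
  else flags <- c(flags, "enl")
  if (length(flags)) attr(out, "flags") <- flags
  out
}

#' Full 18-metric quality report
#'
#' Computes the complete metric suite for one (original, filtered) pair:
#' six error metrics, PSNR, five similarity metrics and six noise/contrast
#' metrics, with shared intermediates computed once.
#'
#' @inheritParams noise_metrics
#' @return A `metric_report` object: named list of the 18 metric values
#'   plus `peak` (255), `c1`, `c2`, `fn_reference` and a character vector
#'   `flags` naming any metrics that were undefined for these inputs.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("ellipses", size = c(32, 32)))
#' rep <- metric_report(ph, ph)
#' rep$ssim
metric_report <- function(orig, filt, fn = NULL, roi_a = NULL, roi_b = NULL) {
  em <- error_metrics(orig, filt)
  sm <- similarity_metrics(orig, filt)
  nm <- noise_metrics(orig, filt, roi_a = roi_a, roi_b = roi_b, fn = fn)
  ps <- if (em$mse == 0) Inf else 10 * log10(255^2 / em$mse)
  flags <- c(attr(em, "flags"), attr(sm, "flags"), attr(nm, "flags"))
  structure(c(em[c("ad", "mse", "rmse")], list(psnr = ps),
              em[c("md", "nae", "nmse")],
              sm[c("sc", "cc", "ncc", "iqi", "ssim")],
              nm[c("cnr", "ni", "asnr", "iv", "nsd", "enl")],
              list(peak = 255, c1 = (0.01 * 255)^2, c2 = (0.03 * 255)^2,
                   fn_reference = nm$fn_reference,
                   flags = if (is.null(flags)) character(0) else flags)),
            class = "metric_report")
}

metric_names <- c("ad", "mse", "rmse", "psnr", "md", "nae", "nmse",
                  "sc", "cc", "ncc", "iqi", "ssim",
                  "cnr", "ni", "asnr", "iv", "nsd", "enl")

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  for (nm in metric_names)
    cat(sprintf("  %-5s %s\n", toupper(nm), format(x[[nm]], digits = 6)))
  if (length(x$flags))
    cat("  undefined:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  data.frame(metric = toupper(metric_names),
             value = vapply(metric_names, function(nm) x[[nm]], numeric(1)),
             row.names = row.names, stringsAsFactors = FALSE)
}
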