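# Independent brute-force oracles and in-code fixtures shared by the suite.

# deterministic random test image on [0, 255]
rand_image <- function(m, n, seed = 1) {
  withr::with_seed(seed, matrix(stats::runif(m * n, 0, 255), m, n))
}

# ---- metric oracles: naive double loops, no shared code with the package ----

oracle_metrics <- function(o, f, fn = NULL) {
  m <- nrow(o); n <- ncol(o)
  s_d <- 0; s_d2 <- 0; s_ad <- 0; s_ao <- 0; s_o2 <- 0; s_f2 <- 0
  s_of <- 0; md <- 0
  for (i in 1:m) for (j in 1:n) {
    d <- o[i, j] - f[i, j]
    s_d <- s_d + d; s_d2 <- s_d2 + d^2; s_ad <- s_ad + abs(d)
    s_ao <- s_ao + abs(o[i, j]); s_o2 <- s_o2 + o[i, j]^2
    s_f2 <- s_f2 + f[i, j]^2; s_of <- s_of + o[i, j] * f[i, j]
    md <- max(md, abs(d))
  }
  mn <- m * n
  mu_o <- sum(o) / mn; mu_f <- sum(f) / mn
  v_o <- 0; v_f <- 0; cv <- 0
  for (i in 1:m) for (j in 1:n) {
    v_o <- v_o + (o[i, j] - mu_o)^2
    v_f <- v_f + (f[i, j] - mu_f)^2
    cv <- cv + (o[i, j] - mu_o) * (f[i, j] - mu_f)
  }
  v_o <- v_o / mn; v_f <- v_f / mn; cv <- cv / mn
  c1 <- (0.01 * 255)^2; c2 <- (0.03 * 255)^2
  mse <- s_d2 / mn
  fn_px <- if (is.null(fn)) NULL else fn
  nsd <- if (is.null(fn_px)) NA_real_ else sqrt(sum((f - fn_px)^2) / mn)
  list(ad = s_d / mn, mse = mse, rmse = sqrt(mse), md = md,
       nae = s_ad / s_ao, nmse = s_d2 / s_o2,
       psnr = 10 * log10(255^2 / mse),
       sc = s_o2 / s_f2, cc = cv / sqrt(v_o * v_f), ncc = s_of / s_o2,
       iqi = 4 * cv * mu_o * mu_f / ((v_o + v_f) * (mu_o^2 + mu_f^2)),
       ssim = (2 * mu_o * mu_f + c1) * (2 * cv + c2) /
         ((mu_o^2 + mu_f^2 + c1) * (v_o + v_f + c2)),
       cnr = abs(mu_o - mu_f) / sqrt(v_o + v_f),
       ni = sqrt(v_f) / mu_f, asnr = mu_f / sqrt(v_f), iv = v_f,
       nsd = nsd,
       enl = if (is.null(fn_px)) NA_real_ else (sum(fn_px) / mn)^2 / nsd^2)
}

# ---- cost / topological derivative oracles ----

# full cost functional, written independently (explicit per-pixel terms,
# summed once at the end to keep accumulation error negligible)
oracle_cost <- function(u, v, k, w) {
  m <- nrow(u); n <- ncol(u)
  terms <- numeric(m * n)
  idx <- 1L
  for (i in 1:m) for (j in 1:n) {
    dx <- if (i < m) u[i + 1, j] - u[i, j] else 0
    dy <- if (j < n) u[i, j + 1] - u[i, j] else 0
    terms[idx] <- w * 0.5 * (u[i, j] - v[i, j])^2 +
      0.5 * k[i, j] * (dx^2 + dy^2)
    idx <- idx + 1L
  }
  sum(terms)
}

# brute-force topological derivative: full re-evaluation per pixel
oracle_dt_field <- function(u, v, k, w, k_low, f_eps) {
  base <- oracle_cost(u, v, k, w)
  out <- matrix(0, nrow(u), ncol(u))
  for (i in seq_len(nrow(u))) for (j in seq_len(ncol(u))) {
    kp <- k; kp[i, j] <- k_low
    out[i, j] <- (oracle_cost(u, v, kp, w) - base) / f_eps
  }
  out
}

# ---- boundary band of a phantom (ground truth for the perturbation mask) ----

boundary_band <- function(regions) {
  m <- nrow(regions); n <- ncol(regions)
  edge <- matrix(FALSE, m, n)
  edge[-m, ] <- edge[-m, ] | (regions[-m, ] != regions[-1, ])
  edge[-1, ] <- edge[-1, ] | (regions[-1, ] != regions[-m, ])
  edge[, -n] <- edge[, -n] | (regions[, -n] != regions[, -1])
  edge[, -1] <- edge[, -1] | (regions[, -1] != regions[, -n])
  band <- edge
  band[-1, ] <- band[-1, ] | edge[-m, ]
  band[-m, ] <- band[-m, ] | edge[-1, ]
  band[, -1] <- band[, -1] | edge[, -n]
  band[, -n] <- band[, -n] | edge[, -1]
  band
}

# ---- minimal DICOM byte builder (independent of the package reader) ----

dcm_le16 <- function(x) as.raw(c(x %% 256, x %/% 256))
dcm_le32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                 (x %/% 65536) %% 256, x %/% 16777216))

dcm_elem_explicit <- function(group, elem, vr, data) {
  if (length(data) %% 2 == 1) data <- c(data, as.raw(0x20))
  hdr <- c(dcm_le16(group), dcm_le16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT"))
    c(hdr, as.raw(c(0, 0)), dcm_le32(length(data)), data)
  else c(hdr, dcm_le16(length(data)), data)
}

dcm_elem_implicit <- function(group, elem, data) {
  if (length(data) %% 2 == 1) data <- c(data, as.raw(0x20))
  c(dcm_le16(group), dcm_le16(elem), dcm_le32(length(data)), data)
}

# Write a small single-frame monochrome DICOM file; `values` is an integer
# matrix of stored pixel values (row-major in the file, as DICOM requires).
write_test_dicom <- function(path, values, explicit = TRUE,
                             slope = NULL, intercept = NULL,
                             spacing = NULL, n_frames = NULL,
                             bits = 16L) {
  ts <- if (explicit) "1.2.840.10008.1.2.1" else "1.2.840.10008.1.2"
  meta <- dcm_elem_explicit(0x0002, 0x0010, "UI", charToRaw(ts))
  el <- function(group, elem, vr, data) {
    if (explicit) dcm_elem_explicit(group, elem, vr, data)
    else dcm_elem_implicit(group, elem, data)
  }
  px_vals <- as.integer(t(values))  # row-major
  px_raw <- if (bits == 16L) {
    as.raw(rbind(px_vals %% 256L, px_vals %/% 256L))
  } else {
    as.raw(px_vals)
  }
  body <- c(
    el(0x0028, 0x0002, "US", dcm_le16(1L)),
    el(0x0028, 0x0004, "CS", charToRaw("MONOCHROME2 ")),
    if (!is.null(n_frames))
      el(0x0028, 0x0008, "IS", charToRaw(as.character(n_frames))),
    el(0x0028, 0x0010, "US", dcm_le16(nrow(values))),
    el(0x0028, 0x0011, "US", dcm_le16(ncol(values))),
    if (!is.null(spacing))
      el(0x0028, 0x0030, "DS",
         charToRaw(paste(spacing, collapse = "\\"))),
    el(0x0028, 0x0100, "US", dcm_le16(bits)),
    el(0x0028, 0x0103, "US", dcm_le16(0L)),
    if (!is.null(intercept))
      el(0x0028, 0x1052, "DS", charToRaw(as.character(intercept))),
    if (!is.null(slope))
      el(0x0028, 0x1053, "DS", charToRaw(as.character(slope))),
    el(0x7FE0, 0x0010, "OW", px_raw))
  out <- c(raw(128), charToRaw("DICM"), meta, body)
  writeBin(out, path)
  invisible(path)
}
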