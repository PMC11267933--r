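test_that("quantum mottle level follows the P^(-3/4) law", {
  expect_equal(quantum_mottle_level(1), 1)
  expect_equal(quantum_mottle_level(16), 0.125)
  expect_equal(quantum_mottle_level(256), 0.015625)
  expect_error(quantum_mottle_level(0), "positive")
  expect_error(quantum_mottle_level(-4), "positive")
})

test_that("quantum mottle injector behaves as a Poisson process", {
  # zero pixels stay zero; huge photon counts leave the image unchanged
  img <- gray_image(matrix(c(0, 128, 255, 0), 20, 20))
  out <- add_quantum_mottle(img, noise_spec("quantum_mottle",
                                            p_avg = 1e6, seed = 5))
  expect_true(all(out$pixels[img$pixels == 0] == 0))
  expect_lt(max(abs(out$pixels - img$pixels)), 1)

  expect_error(add_quantum_mottle(img, noise_spec("gaussian")), "kind")
})

test_that("Poisson variance equals the mean on an unclipped field", {
  flat <- gray_image(matrix(127.5, 100, 100))
  spec <- noise_spec("quantum_mottle", p_avg = 100, seed = 11)
  noisy <- add_quantum_mottle(flat, spec)
  counts <- as.vector(noisy$pixels * spec$p_avg / 255)  # mean 50
  expect_gt(stats::var(counts) / mean(counts), 0.95)
  expect_lt(stats::var(counts) / mean(counts), 1.05)
})

test_that("two-component Gaussian noise has the composed variance", {
  img <- gray_image(matrix(128, 400, 250))
  zero <- add_gaussian(img, noise_spec("gaussian", sigma1 = 0, sigma2 = 0))
  expect_equal(zero$pixels, img$pixels)
  # d_rs = 0 annihilates the first component entirely
  only2 <- add_gaussian(img, noise_spec("gaussian", d_rs = 0,
                                        sigma1 = 100, sigma2 = 0))
  expect_equal(only2$pixels, img$pixels)

  spec <- noise_spec("gaussian", d_rs = 1, sigma1 = 3, sigma2 = 4, seed = 2)
  noisy <- add_gaussian(img, spec)
  emp_sd <- stats::sd(as.vector(noisy$pixels - img$pixels))
  expect_lt(abs(emp_sd - 5) / 5, 0.02)   # sqrt(3^2 + 4^2)
  expect_error(noise_spec("gaussian", sigma1 = -1), "nonnegative")
})

test_that("Rayleigh draws match the analytic distribution", {
  n <- 1e5
  draws <- withr::with_seed(3, rrayleigh_noise(n, g0 = 0, g1 = 4))
  expect_true(all(draws >= 0))
  expect_lt(abs(mean(draws) - sqrt(pi)) / sqrt(pi), 0.02)
  # Kolmogorov-Smirnov distance against the closed-form CDF
  cdf <- function(g) 1 - exp(-g^2 / 4)
  ks <- max(abs(seq_len(n) / n - cdf(sort(draws))),
            abs((seq_len(n) - 1) / n - cdf(sort(draws))))
  expect_lt(ks, 0.01)

  shifted <- withr::with_seed(4, rrayleigh_noise(1e4, g0 = 7, g1 = 10))
  expect_true(all(shifted >= 7))
  expect_error(rrayleigh_noise(5, g1 = 0), "positive")
})

test_that("Rayleigh noise lands on the background mask only", {
  px <- matrix(c(0, 200), 50, 50)   # alternating dark/bright columns-by-rows
  img <- gray_image(px)
  spec <- noise_spec("rayleigh", g0 = 0, g1 = 50, seed = 9)
  noisy <- add_rayleigh_background(img, spec)   # default mask: intensity < 10
  expect_true(all(noisy$pixels[px == 200] == 200))
  expect_true(all(noisy$pixels[px == 0] > 0))

  none <- add_rayleigh_background(img, spec,
                                  background_mask = matrix(FALSE, 50, 50))
  expect_equal(none$pixels, img$pixels)
  expect_error(add_rayleigh_background(img, spec,
                                       background_mask = matrix(TRUE, 2, 2)),
               "dimensions")
})

test_that("samplers reproduce bit-identically under a fixed seed", {
  img <- make_phantom(phantom_spec("ellipses", size = c(32, 32)))
  for (spec in list(noise_spec("quantum_mottle", p_avg = 200, seed = 7),
                    noise_spec("gaussian", seed = 7),
                    noise_spec("rayleigh", seed = 7))) {
    a <- add_noise(img, spec)
    b <- add_noise(img, spec)
    expect_identical(a$pixels, b$pixels)
  }
})

test_that("phantoms are deterministic with exact region intensities", {
  u <- make_phantom(phantom_spec("uniform", size = c(16, 16), contrast = 128))
  expect_equal(u$pixels, matrix(128, 16, 16))

  ck <- make_phantom(phantom_spec("checker", size = c(8, 8), contrast = 255))
  expect_setequal(unique(as.vector(ck$pixels)), c(0, 255))
  expect_equal(ck$pixels[1, 1] != ck$pixels[1, 2], TRUE)

  sp <- phantom_spec("ellipses", size = c(64, 64), contrast = 200)
  el <- make_phantom(sp)
  regions <- attr(el, "regions")
  lev <- 200 * c(0.15, 1, 0.6, 0.35)
  for (r in 0:3)
    expect_equal(mean(el$pixels[regions == r]), lev[r + 1])
  expect_identical(el$pixels, make_phantom(sp)$pixels)

  rg <- make_phantom(phantom_spec("ridge", size = c(64, 64)))
  expect_equal(length(unique(as.vector(rg$pixels))), 3L)
  expect_error(phantom_spec("blob"), "arg")
  expect_error(phantom_spec("uniform", size = c(4, 64)), ">= 8")
})
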