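test_that("ctd_config enforces its invariants", {
  expect_error(ctd_config(k_low = 2, k_high = 1), "k_low")
  expect_error(ctd_config(dt = 0.3), "stability")
  expect_error(ctd_config(threshold_quantile = 1), "quantile")
  expect_error(ctd_config(tol = 0), "tol")
  expect_error(ctd_config(f_epsilon = function(e) -1), "positive")
  cfg <- ctd_config()
  expect_equal(cfg$f_eps_value, pi)
})

test_that("cost functional matches hand computation and the oracle", {
  cfg <- ctd_config()
  u <- matrix(5, 4, 4)
  expect_equal(cost_functional(u, u, matrix(1, 4, 4), cfg), 0)

  # 2x2 checkerboard {0,255}: fidelity 0, every interior forward difference
  # is +-255; pixel (1,1) contributes dx^2 + dy^2, (1,2) and (2,1) one term
  ck <- matrix(c(0, 255, 255, 0), 2, 2)
  hand <- 0.5 * (255^2 + 255^2 + 255^2 + 255^2)
  expect_equal(cost_functional(ck, ck, matrix(1, 2, 2), cfg), hand)

  # doubling the fidelity weight strictly increases the cost when u != v
  v <- matrix(0, 2, 2)
  c1 <- cost_functional(ck, v, matrix(1, 2, 2), ctd_config(fidelity_weight = 1))
  c2 <- cost_functional(ck, v, matrix(1, 2, 2), ctd_config(fidelity_weight = 2))
  expect_gt(c2, c1)

  u8 <- rand_image(8, 8, seed = 2); v8 <- rand_image(8, 8, seed = 3)
  k8 <- matrix(stats::runif(64, 0.5, 1), 8, 8)
  expect_equal(cost_functional(u8, v8, k8, cfg),
               oracle_cost(u8, v8, k8, 1), tolerance = 1e-12)
  expect_error(cost_functional(u8, v8, matrix(1, 4, 4), cfg), "dimensions")
})

test_that("topological derivative field equals the brute-force definition", {
  cfg <- ctd_config()
  u <- matrix(7, 5, 5)
  expect_equal(topological_derivative_field(u, u, matrix(1, 5, 5), cfg),
               matrix(0, 5, 5))

  for (seed in 1:3) {
    u8 <- rand_image(8, 8, seed = seed)
    v8 <- rand_image(8, 8, seed = seed + 10)
    k8 <- matrix(cfg$k_high, 8, 8)
    k8[2, 3] <- cfg$k_low   # one pixel already perturbed
    dt_fast <- topological_derivative_field(u8, v8, k8, cfg)
    dt_brute <- oracle_dt_field(u8, v8, k8, cfg$fidelity_weight,
                                cfg$k_low, cfg$f_eps_value)
    expect_lt(max(abs(dt_fast - dt_brute)), 1e-10)
  }
})

test_that("the derivative singles out a step edge", {
  u <- matrix(0, 3, 3); u[, 3] <- 255   # vertical step between cols 2 and 3
  cfg <- ctd_config()
  dtf <- topological_derivative_field(u, u, matrix(1, 3, 3), cfg)
  expect_true(all(dtf[, 2] < dtf[, 1]))   # edge-owning pixels most negative
  expect_equal(dtf[, 3], rep(0, 3))       # right column has no forward grad
})

test_that("diffusion has the expected fixed points and conserves mass", {
  cfg <- ctd_config()
  u <- matrix(42, 6, 6)
  expect_equal(diffuse(u, u, matrix(1, 6, 6), 25, cfg), u)
  # frozen dynamics: vanishing conductivity and fidelity
  cfg0 <- ctd_config(fidelity_weight = 0, k_low = 1e-12, k_high = 1e-12)
  r <- rand_image(6, 6, seed = 4)
  expect_equal(diffuse(r, r, matrix(1e-12, 6, 6), 10, cfg0), r,
               tolerance = 1e-8)
  # divergence form conserves the global mean without fidelity
  cfgnf <- ctd_config(fidelity_weight = 0)
  out <- diffuse(r, r, matrix(1, 6, 6), 50, cfgnf)
  expect_lt(abs(mean(out) - mean(r)), 50 * 1e-8)
  expect_equal(diffuse(r, r, matrix(1, 6, 6), 0, cfg), r)
})

test_that("relative residual is a scale-free update measure", {
  a <- matrix(100, 4, 4); b <- matrix(101, 4, 4)
  expect_equal(relative_residual(a, a), 0)
  expect_equal(relative_residual(a, b), 0.01)
  expect_equal(relative_residual(3 * a, 3 * b), 0.01)
  expect_warning(r <- relative_residual(matrix(0, 2, 2), matrix(3, 2, 2)),
                 "zero-norm")
  expect_equal(r, 6)
})

test_that("cost is non-increasing across inner diffusion steps", {
  ph <- make_phantom(phantom_spec("ellipses", size = c(32, 32)))
  noisy <- add_gaussian(ph, noise_spec("gaussian", seed = 6))
  cfg <- ctd_config()
  k <- matrix(cfg$k_high, 32, 32)
  u <- noisy$pixels
  prev <- cost_functional(u, noisy$pixels, k, cfg)
  for (s in 1:20) {
    u <- diffuse(u, noisy$pixels, k, 1, cfg)
    cur <- cost_functional(u, noisy$pixels, k, cfg)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("a noise-free constant image is an immediate fixed point", {
  res <- ctd_denoise(gray_image(matrix(50, 16, 16)))
  expect_true(res$converged)
  expect_identical(res$outer_iterations, 1L)
  expect_equal(res$residual_history, 0)
  expect_equal(res$denoised$pixels, matrix(50, 16, 16))
})

test_that("the iteration converges on 64x64 phantoms", {
  for (kind in c("ellipses", "ridge")) {
    ph <- make_phantom(phantom_spec(kind, size = c(64, 64)))
    res <- ctd_denoise(ph)
    expect_true(res$converged)
    expect_lte(utils::tail(res$residual_history, 1), ctd_config()$tol)
    expect_equal(length(res$residual_history), res$outer_iterations)
    expect_false(any(is.na(res$denoised$pixels)))
  }
})

test_that("denoising improves PSNR and SSIM and the run is deterministic", {
  ph <- make_phantom(phantom_spec("ellipses", size = c(64, 64)))
  noisy <- add_gaussian(ph, noise_spec("gaussian", sigma1 = 3, sigma2 = 4,
                                       seed = 7))
  res <- ctd_denoise(noisy)
  expect_gt(psnr(ph, res$denoised), psnr(ph, noisy))
  expect_gt(similarity_metrics(ph, res$denoised)$ssim,
            similarity_metrics(ph, noisy)$ssim)
  res2 <- ctd_denoise(noisy)
  expect_identical(res$denoised$pixels, res2$denoised$pixels)
  expect_identical(res$residual_history, res2$residual_history)
  expect_identical(res$perturbation_mask, res2$perturbation_mask)
})

test_that("perturbation sites concentrate on true region boundaries", {
  ph <- make_phantom(phantom_spec("ellipses", size = c(64, 64)))
  noisy <- add_gaussian(ph, noise_spec("gaussian", sigma1 = 3, sigma2 = 4,
                                       seed = 7))
  res <- ctd_denoise(noisy)
  band <- boundary_band(attr(ph, "regions"))
  frac <- sum(res$perturbation_mask & band) / sum(res$perturbation_mask)
  expect_gte(frac, 0.6)
})

test_that("iteration histories export as a tidy frame", {
  ph <- make_phantom(phantom_spec("ellipses", size = c(32, 32)))
  res <- ctd_denoise(add_gaussian(ph, noise_spec("gaussian", seed = 1)))
  h <- ctd_history(res)
  expect_identical(names(h), c("iteration", "residual", "cost"))
  expect_identical(nrow(h), res$outer_iterations)
  expect_true(all(h$residual >= 0) && all(h$cost >= 0))
})
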