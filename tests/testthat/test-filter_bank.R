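test_that("the bank lists eleven filters with the standard defaults", {
  bank <- list_filters()
  expect_length(bank, 11L)
  names <- vapply(bank, function(f) f$name, character(1))
  expect_identical(names, c("gaussian", "wiener", "laplacian",
                            "laplacian_sharp", "average", "minimum",
                            "median", "pmad", "kuan", "frost",
                            "haar_wavelet"))
  byname <- setNames(bank, names)
  expect_identical(byname$pmad$params$iterations, 15L)
  expect_identical(byname$average$params$window, 7L)
  expect_identical(byname$median$params$window, 3L)
  expect_equal(byname$frost$params$damping, 1)
})

test_that("filter specs validate their parameters", {
  expect_error(filter_spec("sobel"), "unknown filter")
  expect_error(filter_spec("median", list(window = 4)), "odd")
  expect_error(filter_spec("pmad", list(iterations = -1)), ">= 0")
  fs <- filter_spec("pmad", list(iterations = 3L))
  expect_identical(fs$params$iterations, 3L)
  expect_equal(fs$params$kappa, 30)   # untouched defaults survive overrides
})

test_that("constant images are fixed points (Laplacian maps to zero)", {
  flat <- gray_image(matrix(77, 16, 16))
  for (fs in list_filters()) {
    out <- apply_filter(flat, fs)
    if (fs$name == "laplacian") {
      expect_equal(out$pixels, matrix(0, 16, 16), info = fs$name)
    } else {
      expect_equal(out$pixels, flat$pixels, tolerance = 1e-10,
                   info = fs$name)
    }
  }
})

test_that("outputs stay on [0, 255] except the signed Laplacian maps", {
  ph <- make_phantom(phantom_spec("ellipses", size = c(32, 32)))
  noisy <- add_gaussian(ph, noise_spec("gaussian", seed = 3))
  for (fs in list_filters()) {
    out <- apply_filter(noisy, fs)
    if (!fs$name %in% c("laplacian", "laplacian_sharp")) {
      expect_gte(min(out$pixels), 0)
      expect_lte(max(out$pixels), 255)
    }
  }
})

test_that("minimum filter suppresses an isolated bright spike", {
  px <- matrix(0, 9, 9); px[5, 5] <- 255
  out <- apply_filter(gray_image(px), filter_spec("minimum"))
  expect_equal(out$pixels, matrix(0, 9, 9))
})

test_that("median and average behave as their window statistics", {
  px <- matrix(0, 7, 7); px[4, 4] <- 255
  med <- apply_filter(gray_image(px), filter_spec("median"))
  expect_equal(med$pixels, matrix(0, 7, 7))   # spike is an outlier
  avg <- apply_filter(gray_image(px), filter_spec("average"))
  expect_equal(avg$pixels[4, 4], 255 / 49)
})

test_that("PMAD with zero iterations is the identity", {
  img <- gray_image(rand_image(12, 12, seed = 5))
  out <- apply_filter(img, filter_spec("pmad", list(iterations = 0L)))
  expect_identical(out$pixels, img$pixels)
})

test_that("PMAD at huge kappa approaches linear diffusion on a ramp", {
  ramp <- gray_image(matrix(seq(0, 255, length.out = 32), 32, 32,
                            byrow = TRUE))
  pm <- apply_filter(ramp, filter_spec("pmad", list(kappa = 1e9)))
  # 15 steps of step size 0.15 ~ heat diffusion for time 2.25
  gs <- apply_filter(ramp, filter_spec("gaussian",
                                       list(sigma = sqrt(2 * 2.25))))
  interior <- 8:25
  expect_lt(max(abs(pm$pixels[interior, interior] -
                    gs$pixels[interior, interior])), 0.5)
})

test_that("Laplacian kernels produce the documented signed responses", {
  px <- matrix(0, 5, 5); px[3, 3] <- 100
  lap <- apply_filter(gray_image(px), filter_spec("laplacian"))
  expect_equal(lap$pixels[3, 3], -400)
  expect_equal(lap$pixels[2, 3], 100)
  sharp <- apply_filter(gray_image(px), filter_spec("laplacian_sharp"))
  expect_equal(sharp$pixels[3, 3], 100 - (-800))
})

test_that("Haar round-trip without thresholding is exact", {
  for (dims in list(c(16, 16), c(9, 13), c(10, 7))) {
    u <- rand_image(dims[1], dims[2], seed = sum(dims))
    fw <- ctdenoise:::haar2_forward(u, 2L)
    expect_lt(max(abs(ctdenoise:::haar2_inverse(fw) - u)), 1e-8)
  }
})

test_that("Haar shrinkage denoises a noisy flat field", {
  flat <- gray_image(matrix(100, 32, 32))
  noisy <- add_gaussian(flat, noise_spec("gaussian", sigma1 = 0, sigma2 = 5,
                                         seed = 8))
  out <- apply_filter(noisy, filter_spec("haar_wavelet"))
  expect_lt(stats::sd(out$pixels), stats::sd(noisy$pixels))
})

test_that("adaptive filters reduce noise variance on a homogeneous field", {
  flat <- gray_image(matrix(128, 24, 24))
  noisy <- add_gaussian(flat, noise_spec("gaussian", sigma1 = 0, sigma2 = 8,
                                         seed = 13))
  for (name in c("wiener", "kuan", "frost")) {
    out <- apply_filter(noisy, filter_spec(name))
    expect_lt(mean((out$pixels - 128)^2), mean((noisy$pixels - 128)^2))
  }
})
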