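Package: ctdenoise
Title: Continuum Topological Derivative Denoising for CT and MRI Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Denoising of 2-D grayscale medical images (CT, MRI) by an
    iterative continuum topological derivative (CTD) scheme over an isotropic
    conductivity diffusion model: the topological derivative of a restoration
    cost functional locates structural edges, whose conductivity is switched
    low so diffusion removes noise while boundaries are preserved.  Includes
    simulators for the three noise processes the method targets (Poisson
    quantum mottle in CT, additive two-component Gaussian and background
    Rayleigh noise in MRI), deterministic anatomical phantoms, a bank of
    eleven classical comparison filters (Gaussian, Wiener, Laplacian,
    Laplacian sharpening, average, minimum, median, Perona-Malik anisotropic
    diffusion, Kuan, Frost, Haar wavelet shrinkage), an eighteen-metric image
    quality suite (PSNR, SSIM, ENL and others), and a command-line benchmark
    driver producing metric tables and plots.  Reads and writes DICOM
    (single-frame), PNG and TIFF grayscale images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
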