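---
title: "Topological-derivative denoising of CT and MR images: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological-derivative denoising of CT and MR images: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctdenoise)
```

## The restoration model

`ctdenoise` treats a grayscale image as a conductivity medium.  Let $v$ be
the observed (noisy) image on the 0–255 scale and $u$ the restored image.
The restoration cost functional is

$$
\Psi(u) \;=\; \frac{w}{2}\sum_{ij} (u_{ij} - v_{ij})^2
\;+\; \frac{1}{2}\sum_{ij} k_{ij}\,\lvert\nabla u_{ij}\rvert^2 ,
$$

where $\nabla$ is the forward-difference gradient with replicate boundary,
$w$ is the data-fidelity weight, and $k_{ij} > 0$ is a per-pixel
conductivity.  Gradient descent on $\Psi$ is the explicit diffusion update

$$
u \leftarrow u + \Delta t\,\bigl[\operatorname{div}(k\,\nabla u) + w\,(v - u)\bigr],
$$

which `diffuse()` implements in divergence form: with $w = 0$ the global
mean is conserved exactly, and for $\Delta t \le 0.25$ (the 4-neighbour
explicit stability bound at unit conductivity) the cost is non-increasing.

Where the conductivity is high ($k_{\mathrm{high}}$, default 1) the medium
smooths; where it is low ($k_{\mathrm{low}}$, default $10^{-3}$) diffusion
effectively stops.  Denoising therefore reduces to deciding *where* to
switch the conductivity low — and that decision is made by the topological
derivative.

## The topological derivative and the iteration

The topological derivative of $\Psi$ at pixel $\hat x$ is the normalized
cost change when an $\varepsilon$-ball at $\hat x$ (one pixel for
$\varepsilon \le 1$) is switched from $k_{\mathrm{high}}$ to
$k_{\mathrm{low}}$:

$$
D_T(\hat x) \;=\; \frac{\Psi(\Omega_\varepsilon(\hat x)) - \Psi(\Omega)}{f(\varepsilon)},
\qquad f(\varepsilon) = \pi \varepsilon^2 .
$$

Because only the gradient terms owned by $\hat x$ change, the field has the
closed form
$D_T(\hat x) = (k_{\mathrm{low}} - k_{\hat x})\,\lvert\nabla u_{\hat x}\rvert^2 / (2 f(\varepsilon))$,
computed in one pass; the test suite verifies it against a brute-force full
re-evaluation per pixel to $10^{-10}$.  $D_T$ is most negative exactly
where switching the conductivity low removes the most gradient energy:
structural edges and strong outliers.

`ctd_denoise()` alternates three steps until the relative residual
$\lVert u_k - u_{k-1}\rVert_2 / \lVert u_{k-1}\rVert_2$ falls below `tol`
(default $10^{-9}$, realizing a terminal residual of order $10^{-9}$) or
`max_outer` (default 50) is reached:

1. evaluate $D_T$ for the current $(u, k)$;
2. permanently switch to $k_{\mathrm{low}}$ up to a `threshold_quantile`
   fraction (default 2%) of pixels with the most negative derivative, ties
   broken in row-major order;
3. run `max_inner` (default 10) diffusion steps toward the data.

### The significance cut

An unrestricted per-iteration quantile is self-defeating: 2% of all pixels
flagged on each of up to 50 iterations can cover the whole image, at which
point the conductivity field collapses, the fixed point of the diffusion is
the noisy input itself, and the run neither converges nor denoises.  We
therefore restrict flagging to pixels whose derivative is at least
`dt_significance` (default 0.01) times the most negative response observed
on the *first* outer iteration.  The default is chosen on a contrast-vs-noise
argument, not fitted: structural responses scale with the squared edge
contrast (of order $100^2$ for typical 8-bit medical contrast), pure-noise
responses with the noise variance (of order $5^2$), a ratio of about
$2.5\times10^{-3}$; $10^{-2}$ sits between the two scales.  The cut makes
the flag set self-limiting — once the image is smooth away from edges, no
new site is significant, the conductivity field freezes, and the iteration
contracts geometrically to its fixed point.  Setting `dt_significance = 1`
disables the cut and restores the unrestricted quantile rule.

With the defaults, a noisy 256 × 256 phantom converges in about 8 outer
iterations with a final residual near $2\times10^{-10}$, and the
perturbation mask concentrates (95% within one pixel) on the true region
boundaries.

### Degenerate inputs and numerical choices

* A constant noise-free image is an immediate fixed point: one outer
  iteration, residual exactly 0, `converged = TRUE`.
* A zero-norm previous iterate makes the relative residual fall back to the
  absolute norm, with a warning.
* Conductivity switches are permanent within a run (the create-holes
  semantics of topology optimization); healing variants are out of scope.
* All computation is on the 255 scale regardless of acquisition depth,
  because the quality metrics are defined against the 8-bit peak;
  `to_unit_range()` maps arbitrary-depth inputs onto it (a constant image
  maps to zero).
* Replicate boundaries are used everywhere — diffusion, filters,
  convolution — so no energy is injected at the frame.

## Noise models

Three processes cover the targeted modalities.

* **Quantum mottle (CT).**  Photon starvation is Poisson on a
  pixel-by-pixel basis: a pixel of value $v$ maps to an expected count
  $\lambda = v\,P_{\mathrm{avg}}/255$, a Poisson draw is taken and scaled
  back.  The classical mottle-level formula
  $\sqrt{P^{SD}}/P_{\mathrm{avg}}$ with $P^{SD} = \sqrt{P_{\mathrm{avg}}}$
  (i.e. $P_{\mathrm{avg}}^{-3/4}$) is exposed separately as
  `quantum_mottle_level()`; the injector itself is the Poisson mechanism.
* **Two-component Gaussian (MRI).**  $N = \sqrt{d_{rs}}\,N_1 + N_2$ with
  independent zero-mean components of standard deviations
  $\sigma_1, \sigma_2$.  The scale factor $d_{rs}$ is a free nonnegative
  parameter (default 1).
* **Rayleigh background (magnitude MRI).**  Density
  $(2/g_1)(g - g_0)\exp\!\bigl(-(g-g_0)^2/g_1\bigr)$ for $g \ge g_0$ — the
  sign of the exponent must be negative for the curve to be a density; the
  positive-exponent variant sometimes printed is non-normalizable.  Draws
  are added to background pixels only by default (intensity < 10), with an
  explicit mask for other conventions, since this noise lives in the air
  background of magnitude MR images.

Sampler correctness is property-tested: Poisson variance/mean within
[0.95, 1.05] on $10^4$ draws, Kolmogorov–Smirnov distance of $10^5$
Rayleigh draws below 0.01 against the closed-form CDF
$1 - \exp(-(g-g_0)^2/g_1)$.

## Synthetic phantoms — what they emulate and what they do not

Clinical CT/MR images are not redistributable, so experiments run on
deterministic phantoms: `ellipses` (nested ellipses of distinct
intensities, a ventricle-like object), `ridge` (a dark Y-shaped airway
ridge on bright lung-like ellipses, a carina-like object), plus `checker`
and `uniform` test patterns.  They reproduce the features that matter to a
diffusion denoiser — homogeneous regions, curved boundaries, thin dark
structures — with exactly known ground truth, which is what makes PSNR
against a clean reference and boundary-mask overlap measurable at all.

They do **not** reproduce partial-volume blur, anatomical texture,
reconstruction artifacts, spatially varying noise, or scanner-specific
transfer functions.  Passing the synthetic suite therefore shows the
algorithm removes the modelled noise processes while preserving piecewise
structure; it does not certify clinical image quality, which the original
protocol assesses radiologically.

### Study conditions

The benchmark defaults are: 256 × 256 phantoms; quantum mottle
$P_{\mathrm{avg}} = 1000$ (≈7 grey-level SD at peak intensity); Gaussian
$d_{rs}=1, \sigma_1=3, \sigma_2=4$ (combined SD 5, ≈2% of range); Rayleigh
$g_0=0, g_1=50$ (mode $\sqrt{g_1/2}=5$ grey levels, a realistic MR
background floor) applied to the phantom's anatomical background region.
Unit and property tests use 8–64 pixel squares so the default suite runs
in seconds.

A known limitation follows from the Rayleigh model itself: its draws have
mean $\sqrt{\pi g_1}/2$ (≈6.3 grey levels at the default), and an additive
*positive-mean* corruption leaves a deterministic bias that no
data-fidelity-anchored restoration can remove.  PSNR against the clean
reference therefore saturates at the bias floor for Rayleigh runs even
though the stochastic part is removed and PSNR/SSIM still strictly
improve.  The two zero-mean processes reach the mid-40 dB range on the
phantom analog.

## The comparison filter bank

Eleven classical denoisers are provided behind one interface
(`apply_filter()`), with the conventional parameterizations: Gaussian
convolution (σ = 1), local adaptive Wiener (3 × 3, noise variance
estimated as the mean local variance), 4-neighbour Laplacian (signed edge
map), Laplacian sharpening with the all-ones −8-centre kernel (signed),
7 × 7 average, 3 × 3 minimum and median, Perona–Malik anisotropic
diffusion (exponential conductance, κ = 30, λ = 0.15, 15 iterations), Kuan
and Frost speckle filters (3 × 3; Frost damping 1), and 2-level Haar
shrinkage with VisuShrink soft thresholding
($\hat\sigma\sqrt{2\ln(mn)}$, $\hat\sigma$ from the MAD of the finest
diagonal band).  Window sizes and conductance/damping choices that the
comparison protocol leaves unstated use these conventional defaults and
are all overridable through `filter_spec()`.  The two Laplacian variants
deliberately return signed maps; they are clipped only when exported as
images.

## The metric suite

`metric_report()` computes the 18 measures — AD, MSE, RMSE, PSNR
($10\log_{10}(255^2/\mathrm{MSE})$), MD, NAE, NMSE, SC, CC, NCC, IQI,
SSIM, CNR, NI, ASNR, IV, NSD, ENL — as single global formulas (population
moments over the whole image, not sliding windows), with the standard SSIM
stabilizers $c_1 = (0.01\cdot255)^2$, $c_2 = (0.03\cdot255)^2$.  Design
choices where the printed definitions are underdetermined:

* The noise-free reference $I^{Fn}$ in NSD/ENL is the clean image when one
  is available (the synthetic setting); otherwise a 7 × 7
  average-smoothed copy of the filtered image stands in.  The choice is
  recorded in the report's `fn_reference` field.
* CNR defaults to whole-image statistics; explicit two-ROI masks are
  supported.
* Degenerate cases (constant images, zero denominators) return `NA` values
  listed in the report's `flags` field — never errors mid-report, and
  PSNR/ASNR use an infinity marker where exact equality makes them
  unbounded.

Every metric is tested against an independent double-loop oracle to
$10^{-8}$, along with the algebraic identities
$\mathrm{RMSE}^2 = \mathrm{MSE}$, $\mathrm{NI}\cdot\mathrm{ASNR} = 1$, and
the symmetry/invariance properties of SSIM, IQI and CC.

## Reproducible benchmarks

`run_experiment()` chains phantom → noise → all filters + CTD → metric
table, writing images, `metrics.csv` (18 rows × one column per method),
the CTD residual history, optional per-metric bar panels and a JSON
manifest.  A single master seed fans out deterministically to the stages;
identical configuration and seed reproduce `metrics.csv` byte for byte.
The `ctdenoise` command-line script exposes the same pipeline
(`phantom`, `noise`, `denoise`, `metrics`, `bench` subcommands) for shell
use.

```{r example, eval = FALSE}
clean <- make_phantom(phantom_spec("ellipses", size = c(256, 256)))
noisy <- add_gaussian(clean, noise_spec("gaussian", sigma1 = 3, sigma2 = 4))
res <- ctd_denoise(noisy)
psnr(clean, noisy); psnr(clean, res$denoised)
```

## Known limitations

* 2-D single-frame images only; no volumes, no multi-frame DICOM.
* DICOM support is a minimal little-endian reader (explicit and implicit
  VR) sufficient for exported CT/MR frames; compressed transfer syntaxes
  are rejected, and DICOM writing is not supported.
* The global (single-window) SSIM/IQI are the printed definitions; they
  are less discriminative than sliding-window variants.
* Rician noise and k-space simulation are out of scope; the Rayleigh model
  applies to background only.
* The Rayleigh mean bias limits PSNR-vs-clean for that process, as
  discussed above.
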