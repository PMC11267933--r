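# ctdenoise

Denoising of 2-D grayscale medical images (CT, MRI) with a **continuum
topological derivative (CTD)** iteration, together with the noise models it
targets, a bank of eleven classical comparison filters, an 18-metric image
quality suite, synthetic anatomical phantoms and a reproducible benchmark
driver with a command-line interface.

## Who this is for

Researchers in medical image processing who need (a) a self-contained,
testable implementation of topological-derivative denoising for CT/MR-style
images, (b) simulators for the three noise processes that dominate those
modalities — Poisson quantum mottle (CT), additive two-component Gaussian
and background Rayleigh noise (MRI) — and (c) a level playing field for
comparing denoisers: the same boundary conventions, the same metric
formulas, the same seeds.

## The method

The image plane is modelled as an isotropic conductivity medium.  For the
noisy observation $v$ and restored image $u$, the restoration cost is

$$
\Psi(u) = \frac{w}{2}\sum_{ij}(u_{ij}-v_{ij})^2
 + \frac{1}{2}\sum_{ij} k_{ij}\lvert\nabla u_{ij}\rvert^2 ,
$$

with per-pixel conductivity $k_{ij}$.  The **topological derivative**

$$
D_T(\hat x) = \frac{\Psi(\Omega_\varepsilon(\hat x)) - \Psi(\Omega)}{f(\varepsilon)},
\qquad f(\varepsilon)=\pi\varepsilon^2,
$$

measures the cost change of switching the conductivity at $\hat x$ from
$k_{\mathrm{high}}$ to $k_{\mathrm{low}}$ — most negative at structural
edges.  Each outer iteration flags the most significant negative-derivative
pixels (edges stop diffusing; structure is retained), then runs explicit
conductivity diffusion $u \leftarrow u + \Delta t[\mathrm{div}(k\nabla u) +
w(v-u)]$ toward the data, until the relative residual
$\lVert u_k-u_{k-1}\rVert/\lVert u_{k-1}\rVert$ drops below $10^{-9}$.
The per-pixel derivative is computed in closed form and verified against
the brute-force definition in the test suite.  See the methods vignette
(`vignettes/ctd-denoising.Rmd`) for the full model, parameter rationale and
limitations.

## Worked example

```r
library(ctdenoise)

clean <- make_phantom(phantom_spec("ellipses", size = c(256, 256)))
noisy <- add_gaussian(clean, noise_spec("gaussian", sigma1 = 3, sigma2 = 4,
                                        seed = 1))
res <- ctd_denoise(noisy)
res
#> <ctd_result> 8 outer iterations, converged, final residual 2.2e-10
#>   perturbation sites: 1311 (2.00% of pixels)

psnr(clean, noisy)          # 34.11 dB
psnr(clean, res$denoised)   # 44.19 dB
```

The denoiser converges in 8 outer iterations to a relative residual of
`2.2e-10`, flags 2% of pixels as perturbation sites (they sit on the
phantom's region boundaries), and raises PSNR against the clean reference
from 34.1 to 44.2 dB.  The full quality report:

```r
metric_report(clean, res$denoised, fn = clean)
#> <metric_report>
#>   AD    -0.00298008
#>   MSE   2.4769
#>   RMSE  1.57382
#>   PSNR  44.1917
#>   MD    11.2129
#>   NAE   0.0136365
#>   NMSE  0.000180816
#>   SC    0.999696
#>   CC    0.999772
#>   NCC   1.00006
#>   IQI   0.999772
#>   SSIM  0.999773
#>   CNR   2.85949e-05
#>   NI    0.810474
#>   ASNR  1.23385
#>   IV    5432.41
#>   NSD   1.57382
#>   ENL   3338.71
```

Error metrics (AD/MSE/RMSE/MD/NAE/NMSE) are near zero, similarity metrics
(SC/CC/NCC/IQI/SSIM) near one, and NSD/ENL quantify the residual noise
against the clean reference.

A full comparison against the eleven classical filters:

```r
out <- run_experiment(experiment_config(
  input = phantom_spec("ellipses"), noise = noise_spec("gaussian"),
  filters = list_filters(), ctd = ctd_config(),
  output_dir = "bench", seed = 1))
out$metrics          # 18 metrics x 12 methods, also written to bench/metrics.csv
```

Or from a shell:

```sh
Rscript inst/cli/ctdenoise.R phantom --kind ellipses --size 256x256 --out clean.png
Rscript inst/cli/ctdenoise.R noise --kind gaussian --sigma1 3 --sigma2 4 --seed 1 \
    --in clean.png --out noisy.png
Rscript inst/cli/ctdenoise.R denoise --in noisy.png --out denoised.png --ctd
Rscript inst/cli/ctdenoise.R metrics clean.png denoised.png
```

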