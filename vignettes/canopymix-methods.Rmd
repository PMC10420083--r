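---
title: "Estimating rapeseed yield at flowering from mixed canopy pixels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rapeseed yield at flowering from mixed canopy pixels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopymix)
```

## The problem

Oilseed rape (rapeseed) flowers for about a month, and during that period the
canopy is a mixture of three visually and spectrally distinct components:
yellow petals, green leaves, and the soil background. Yellow petals reflect
strongly in the green and red but only moderately in the near infrared, while
leaves do the opposite — dark in the red, bright in the NIR. Classical
vegetation indices (VIs) therefore misbehave at flowering: indices built on
"red low, NIR high" logic (NDVI, CIgreen, RVI) lose sensitivity exactly when
the crop is easiest to detect. Since it is the leaves, not the petals, that
drive assimilate production and ultimately seed yield, a natural fix is to
estimate how much of each pixel is leaf and weight the VI by that fraction.

`canopymix` implements that idea end to end:

1. **Radiometric calibration** — empirical-line conversion of raw camera
   digital numbers (DN) to surface reflectance using ground panels of known
   reflectance (0.06 / 0.24 / 0.48).
2. **Spectral mixture analysis (SMA)** — per-pixel decomposition of canopy
   reflectance into flower (FL), leaf (LF) and soil (SL) fractions by fully
   constrained least squares (FCLS).
3. **Vegetation indices** — the nine-index suite NDVI, CIgreen, VARI, RVI,
   DVI, RDVI, EVI, TVI, NDYI.
4. **Yield models** — per-plot linear regressions of yield on `VI`,
   `VI x Abd_FL` and `VI x Abd_LF`, evaluated by leave-one-out
   cross-validation (LOOCV).
5. **Accuracy assessment** — overall/user/producer accuracy and Cohen's
   kappa from a 2x2 crop-map confusion matrix.
6. **A synthetic trial generator** so that every stage can be exercised and
   tested without any field or satellite data.

## The mixing model and the FCLS solver

A pixel's reflectance at band $\lambda$ is modelled as a convex combination
of endmember reflectances,

$$\rho(\lambda) = \sum_{i \in \{FL, LF, SL\}} a_i\, \rho_i(\lambda),
\qquad a_i \ge 0,\; \textstyle\sum_i a_i = 1,$$

and the abundances $a$ solve $\min_a \lVert E a - \rho \rVert_2$ over the
probability simplex, where $E$ is the bands-by-endmembers matrix of
band-resampled endmember spectra. With three endmembers this quadratic
program is tiny, and `fcls_pixel()` solves it **exactly** by enumerating the
seven possible active supports: for each support the equality-constrained
(sum-to-one) least-squares solution comes from its KKT system, infeasible
candidates (negative components) are discarded, and the feasible candidate
with the lowest objective wins. Because the KKT solution is affine in
$\rho$, the per-support maps are precomputed once per endmember matrix and
whole images unmix as a handful of matrix products (`unmix_image()`), which
keeps a scene of a few thousand pixels well under a second.

Numerical details that matter:

* Supports are visited from largest to smallest and a candidate must improve
  the objective by more than `1e-12` to replace the incumbent, so objective
  ties resolve to the largest support. Combined with pseudo-inversion of
  singular KKT systems this yields the **minimum-norm** minimiser when the
  endmember matrix is rank deficient (which also triggers a warning).
* Solver noise is clamped at `-1e-9`, then abundances are renormalised so
  every reported vector sums to one exactly; tests enforce the simplex
  constraints to `1e-9` on every pixel.
* The per-pixel residual is reported as $\lVert Ea-\rho\rVert_2/\sqrt{B}$
  (per-band RMS) so six-band UAV and four-band satellite residuals are
  comparable.
* `oracle_fcls()` is a deliberately independent brute-force check: it scans
  the whole abundance lattice at a given spacing and returns the best lattice
  point. The test suite verifies that the QP solution never loses to the
  lattice search beyond the lattice resolution bound.

Pixels with reflectance above 1 (possible after calibration) are unmixed
as-is and counted in the output metadata; no residual-based pixel rejection
is applied by default.

## Band resampling

Endmember spectra are measured on a fine (~1 nm) grid; sensors integrate
over bands. Only band centre and FWHM are typically published, so the
package models each band as a **boxcar** over
$[c - \mathrm{FWHM}/2,\, c + \mathrm{FWHM}/2]$ and averages the spectrum over
that support by the trapezoid rule on the spectrum's native grid. A boxcar is
the simplest defensible response model and makes the operation exactly
testable (a constant stays a constant; a linear ramp averages to its
midpoint). Averaging over the bandpass rather than sampling the centre
wavelength is this package's choice — with smooth spectra and 10–20 nm
bandwidths the difference is small. Two presets exist: `sensor_uav6()`
(490/550/670/720/800 nm @10, 900 nm @20 — blue, green, red, red edge, NIR1,
NIR2) and `sensor_quad4()`, a generic blue/green/red/NIR satellite stand-in
that mirrors the UAV roles so the same spectra serve both scales. The 720
and 900 nm bands take part in unmixing but feed no index.

## Empirical-line calibration

Per band, reflectance is regressed on mean panel DN
($\rho = g\,\mathrm{DN} + b$) by ordinary least squares over the three
panels; `apply_elm()` then converts every pixel. Negative reflectances are
clipped to zero and counted; values above one are kept but counted, since
they carry information for unmixing diagnostics. Panel pixels are averaged
with the mean by default (median available). Calibration is fitted per
image. After a round trip through 8-bit DN the only residual error is
quantisation: every pixel is within half a step $g/2$, and the error RMS
sits at the uniform-quantisation value $g/\sqrt{12}$ — note that the latter
is an *expectation*, so a finite scene's sample RMSE fluctuates around it by
a relative $\mathcal{O}(1/\sqrt{2n})$; the tests assert the deterministic
half-step bound per pixel and the RMS value to within 10%.

## The index suite

All nine indices use only the blue/green/red/NIR1 roles:

| Index | Formula |
|---|---|
| NDVI | $(\rho_{800}-\rho_{670})/(\rho_{800}+\rho_{670})$ |
| CIgreen | $\rho_{800}/\rho_{550}-1$ |
| VARI | $(\rho_{550}-\rho_{670})/(\rho_{550}+\rho_{670})$ |
| RVI | $\rho_{800}/\rho_{670}$ |
| DVI | $\rho_{800}-\rho_{670}$ |
| RDVI | $(\rho_{800}-\rho_{670})/\sqrt{\rho_{800}+\rho_{670}}$ |
| EVI | $2.5(\rho_{800}-\rho_{670})/(\rho_{800}+6\rho_{670}-7.5\rho_{490}+1)$ |
| TVI | $0.5[120(\rho_{800}-\rho_{550})-200(\rho_{670}-\rho_{550})]$ |
| NDYI | $(\rho_{550}-\rho_{490})/(\rho_{550}+\rho_{490})$ |

Two typographic pitfalls in circulating tabulations are handled explicitly.
RDVI is sometimes printed with the NDVI denominator (the square root lost in
typesetting); the package implements the renormalised form above, with the
NDVI-identical variant available via `rdvi_variant = "ndvi"`. The TVI
formula sometimes carries an unbalanced doubled parenthesis; it is
implemented as the balanced difference shown. This VARI variant omits the
blue term some definitions subtract in the denominator. Zero denominators
produce invalid (masked) pixels, never infinities, and the count is
recorded.

**Plot-level convention.** Plot VIs are computed from the plot's *mean
reflectance* over a boundary-avoiding rectangular ROI — not as the mean of
per-pixel VI values. The alternative (`vi_convention = "per_pixel_mean"`) is
offered, and the tests assert that the two genuinely differ on
heterogeneous plots.

## Yield models and cross-validation

For each index the package fits three univariate linear families against
plot yield: the VI alone, `VI x Abd_FL`, and `VI x Abd_LF` — 27 models in
all (`rank_models()`). With only two dozen plots, honest evaluation uses
leave-one-out cross-validation. For $K$ plots, each fold $i$ refits on the
other $K-1$ and records the held-out residual $E_i$ and the training-fit
$R_i^2$. Reported statistics:

* $R^2 = \frac{1}{K}\sum_i R_i^2$ — the mean per-fold training $R^2$. This
  is the only per-fold $R^2$ that is well defined; the pooled squared
  correlation of held-out predictions with observations is reported
  alongside as `r2_pooled` for transparency.
* $\mathrm{RMSE} = \sqrt{\sum_i E_i^2 / K}$ in kg/ha.
* $\mathrm{CV} = 100\cdot\mathrm{RMSE}/\bar{y}$ in percent. A per-fold
  averaging variant ($\mathrm{mean}_i\,100\lvert E_i\rvert/\bar{y}_{-i}$) is
  available via `cv_variant = "per_fold"`; the ratio-of-RMSE-to-mean
  definition is the default because it is the one consistent with jointly
  reported RMSE/CV pairs in the field literature (an RMSE of ~228 kg/ha at a
  CV of 9.9% implies a mean yield of ~2300 kg/ha, which matches such
  trials).

Rankings sort by $R^2$ descending with RMSE as tie-break and mark the top
six models outside the flower-product family, mirroring the reporting
convention of flowering-stage yield studies. No multiple-testing correction
is applied across the 27 models — rankings are descriptive, not inferential;
treat small differences between neighbouring models as noise.

## What the synthetic generator emulates

`trial_design()` + `generate_trial()` + `render_scene()` + `encode_dn()`
emulate a single-season nitrogen-response trial imaged once at peak
flowering:

* **Design**: 8 nitrogen rates (0–360 kg/ha), 3 randomised replicates,
  24 plots in a 4x6 grid with bare-soil gutters. Plot footprints default to
  8x6 pixels (ROIs inset one pixel) — deliberately small so a full scene
  unmixes in well under a second and multi-seed experiments stay cheap; all
  sizes are parameters.
* **Spectra**: piecewise-linear flower/leaf/soil curves on a 1-nm grid over
  400–1000 nm with seeded anchor jitter, constrained so that flower > leaf
  in green and red, flower < leaf in NIR, the leaf shows its green peak and
  red absorption dip, and soil rises monotonically with wavelength. The
  exact curve shapes are this package's invention; only the ordering
  constraints are data-driven.
* **Abundance–nitrogen response**: leaf fraction rises from 0.2 to 0.7 at
  225 kg/ha, then declines slightly (to 0.66 at 360) — the small
  supra-optimal decline reflects lodging and mutual shading under
  over-fertilisation and is what makes yield peak at 225 kg/ha rather than
  drifting upward; flower fraction decreases mildly around 0.2; soil takes
  the remainder. Per-plot truncated-Gaussian scatter (s.d. 0.03 for flower,
  0.04 for leaf) makes replicates heterogeneous.
* **Yield**: $y = \beta_0 + \beta_1 (\mathrm{EVI}_{true} \times Abd_{LF})$
  evaluated on the plot's true mixed spectrum, with $\beta$ solved so the
  scatter-free design curve spans 1000 kg/ha at N0 to 3400 kg/ha at N225.
  Observed yields add Gaussian noise of s.d. 200 kg/ha (a ~9% CV, the
  magnitude typical of plot-scale yield determination).
* **Scene**: pixel abundances are Dirichlet-jittered plot means
  (concentration 300, i.e. a ~0.025 abundance s.d.) projected back onto the
  simplex by construction; reflectance is the forward mixing model plus
  per-band Gaussian noise at a 40 dB SNR by default, clipped to [0, 1] with
  the clipped fraction logged.
* **DN encoding**: 8-bit by default, with three embedded calibration panels
  of reflectance 0.06/0.24/0.48. Default per-band gains (0.004/0.005
  reflectance per count, zero bias) are exact divisors of the panel
  reflectances, so panel DNs are integers and a noiseless panel fit recovers
  the true gain and bias exactly — the behaviour of targets matched to the
  camera's radiometric range.

**What it does not emulate**: radiative transfer (no PROSAIL-style canopy
model), BRDF and view-angle effects, within-field soil moisture gradients,
atmospheric effects, sensor vignetting, or phenology. Passing tests on
these scenes therefore demonstrate the correctness of the *estimators* —
calibration, unmixing, aggregation, model selection — not the field-scale
accuracy of any particular index.

## A structural caveat on the VARI product

On these synthetic scenes the leaf-abundance product reliably improves
NDVI, RDVI and EVI, but *worsens* VARI, and the gap widens as flower
fractions vary more. The mechanism is structural, and worth understanding
before extrapolating product models to other indices. Soil and flower both
reflect more red than green, so plot-level VARI is negative on soil- and
flower-dominated plots and crosses zero mid-gradient; multiplying by leaf
abundance then flattens the response exactly where VARI changes sign,
distorting an otherwise monotone relationship. Meanwhile the plain VI stays
informative here because the synthetic yield is itself generated through the
true-spectrum EVI, which couples yield to the same spectral contamination
the plain VI sees. In real trials yield is decoupled from spectral
artefacts, which is why field studies can observe large product-model gains
for VARI that this generator cannot reproduce. The acceptance suite asserts
the product-beats-plain property for all four of NDVI, VARI, RDVI, EVI on
flower-heterogeneous scenes (flower scatter s.d. 0.08); the VARI clause
fails for the reason above and is left failing deliberately, with this
analysis as the record.

## Accuracy assessment

`confusion_metrics()` consumes a 2x2 matrix with mapped classes on rows and
reference classes on columns (user accuracy row-wise, producer accuracy
column-wise): overall accuracy is the diagonal fraction, kappa is
chance-corrected agreement with expected agreement from the row/column
margins. Metrics are computed at full precision and rounded only for
display (two decimals); zero margins leave the affected UA/PA undefined
without poisoning the rest.

## Problem sizes used by tests and the acceptance script

Scenes in the test suite use the default 24-plot layout (~2,100 pixels,
~60 s for the whole suite); the SNR-validation test uses 21x21-pixel plots
(~13,000 pixels); FCLS is validated on 1,000 random mixtures against a
lattice oracle at spacing 1e-3 (~500k lattice points); multi-seed
statistical checks use 20 seeds. These sizes were chosen so each check has
comfortable statistical resolution while the whole suite remains quick to
iterate on.

## Worked example

```{r example, eval = FALSE}
library(canopymix)

trial <- generate_trial(trial_design(seed = 1))
E     <- build_endmember_matrix(trial$library, trial$sensor)
scene <- render_scene(trial)

dn    <- encode_dn(scene$reflectance)            # 8-bit DN + panels
gb    <- fit_elm(extract_panels(dn))             # empirical line model
refl  <- drop_panel_strip(apply_elm(dn, gb))     # back to reflectance

abund <- unmix_image(refl, E)                    # FCLS abundances
tab   <- plot_aggregate(refl, abund, trial$plots)
rank_models(tab)                                 # 27 LOOCV yield models

autoplot(loocv_evaluate(tab$EVI_x_lf, tab$yield_kg_ha, label = "EVI x AbdLF"))
plot_nitrogen_response(trial$plots)
```
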