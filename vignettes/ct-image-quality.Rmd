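---
title: "Task-based CT image quality: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based CT image quality: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiq)
```

## What this package models

Modern CT reconstructions — hybrid iterative (HIR), model-based iterative
(MBIR) and deep-learning (DLR) families — are non-linear, so classical
MTF and pixel-SD summaries mislead: resolution depends on the task
contrast, and two images with the same noise SD can look entirely
different because their noise *textures* (spectral content) differ. MBIR
in particular concentrates noise power at low spatial frequencies, which
radiologists describe as an "oil painting" appearance. `ctiq` implements
the measurement chain used to characterize such reconstructions:

* a **task-based transfer function (TTF)**: the MTF measured at a fixed
  task contrast from the circular edge of a cylindrical phantom insert,
  via the radial edge-spread function (ESF), its derivative (LSF), and
  the normalized Fourier magnitude;
* a **noise power spectrum (NPS)**: the ensemble periodogram of
  detrended uniform-region patches, whose integral equals the noise
  variance, with a radial 1D curve and band-split summaries;
* **clinical ROI metrics**: objective noise (mean ROI SD over patients),
  two contrast-to-noise ratios (liver vs psoas over upper-fat noise;
  pelvic organ vs bladder over lower-fat noise), effective dose
  (DLP x k, k = 0.015 mSv mGy^-1 cm^-1 for the abdomen/pelvis), and
  weight-based contrast-material arithmetic;
* the **paired statistics** used to compare two reconstruction arms:
  paired t for continuous rows, Wilcoxon signed-rank for 5-point ordinal
  ratings, Welch t for group body-size checks, and weighted kappa for
  inter-reviewer agreement.

Because the scanner images behind such studies are rarely shared, the
package also ships a **synthetic generator** for each stage, with known
ground truth: rendered phantoms, reconstruction emulation (Gaussian blur
plus correlated noise of chosen spectral shape), and a paired clinical
cohort.

## The phantom and reconstruction emulation

`render_phantom()` rasterizes a disk or elliptical body with cylindrical
inserts. Two built-ins mirror common QA hardware: `qa_phantom()`, a
water disk with inserts at the standard material HU values (air -1000,
polypropylene -105, water 0, acrylic 120, Delrin 340, Teflon 940), and
`abdomen_phantom()`, a uniform 330 x 220 mm ellipse for noise work. The
acrylic insert (+120 HU) is the default TTF target because its contrast
approximates soft tissue against fat, the task relevant to oncologic
follow-up imaging.

Boundary pixels are antialiased by **area fraction**: each pixel cut by
a region boundary receives the coverage-weighted blend of the two
materials. Coverage is computed numerically on a 16 x 16 subpixel grid
confined to the pixels that can straddle the boundary; the residual
coverage error (< 0.4% of a pixel) is negligible against every stated
tolerance, and the same code serves disks and ellipses. The
`antialias = FALSE` mode reproduces plain pixel-centre sampling and is
kept as the brute-force oracle used in the tests. One consequence worth
remembering: an antialiased edge is a step *pre-filtered by the pixel
aperture*, so closed-form comparisons against a Gaussian-blurred edge
must use `sigma_eff^2 = sigma^2 + spacing^2 / 12`.

A `recon_model()` emulates a reconstruction arm with two knobs:

* `blur_sigma` (mm) — an isotropic Gaussian PSF, applied by
  `apply_recon_blur()` as a separable discrete kernel with replicate
  padding (kernel radius 4 sigma, kernel normalized, so uniform fields
  and spatial means are preserved exactly);
* `nps_shape` — a radial spectral density, drawn from a two-lobe family
  `w1 exp(-f^2/2 s1^2) + w2 f exp(-f^2/2 s2^2)`. The first (low-pass)
  lobe emulates low-frequency-heavy textures, the second (band-pass)
  lobe finer grain. The presets `recon_mbir_like()`, `recon_dlr_like()`
  and `recon_hir_like()` are positioned so that the MBIR-like arm is
  smoother (blur 0.55 mm) and low-frequency-heavy while the DLR-like arm
  is sharper (0.35 mm) with a band-pass texture — an *emulation* of the
  qualitative behaviour of those families, not a claim about any
  vendor's algorithm.

`synthesize_noise()` filters white Gaussian noise in the frequency
domain with `sqrt(nps_shape(f))`, normalizing the filter's mean-square
gain to 1 so the pixel variance equals `noise_sd^2` in expectation (the
field stays exactly stationary Gaussian; per-realization rescaling would
distort that). Every draw takes an explicit integer seed, recorded in
the output's `"seed"` attribute.

`simulate_scan()` chains render, blur and noise. Its dose control
mirrors scanner automatic exposure control (AEC): the **noise index** is
defined as the target SD at 5 mm slice thickness, so a thin slice of
thickness `t` receives SD `noise_index * sqrt(5 / t)` (variance
inversely proportional to averaged thickness). At a noise index of
35 HU and 0.5 mm slices this gives 35 sqrt(10) = 110.7 HU. Real AEC
internals are proprietary, so a model's explicit `noise_sd` always
overrides the mapping.

## TTF estimation

The chain follows the standard circular-edge recipe:

1. `estimate_center()` — intensity-weighted centroid of the thresholded
   insert, refined once; rejects targets whose local contrast is below
   20 HU (configurable), since a centroid on noise is meaningless.
2. `extract_radial_esf()` — every pixel in an annulus around the edge
   contributes (distance to centre − nominal radius, HU); the circular
   geometry makes the signed edge distance sample almost continuously,
   so the default bin width of 0.1 pixel keeps all bins populated while
   oversampling the edge ~10x. Slices of a stack pool their samples at
   this level (not by averaging final TTFs), which weights all data
   equally and keeps the ESF noise model simple.
3. `esf_to_lsf()` — linear resampling to the uniform bin grid, optional
   Savitzky-Golay smoothing (off by default: smoothing before
   differentiation biases the TTF downward, and the oversampled ESF is
   usually clean enough), then central differences. The LSF is oriented
   to positive area; its integral estimates the edge contrast.
4. `lsf_to_ttf()` — tail baseline (mean of the outer 10% of samples on
   each side) subtracted, a Hann window centred on the LSF peak applied
   to suppress tail noise, then the DFT magnitude normalized to 1 at DC.
   `ttf_at_fraction()` interpolates f50/f10 summaries.

On a noiseless rendered disk blurred with sigma = 0.5 mm the estimated
curve stays within 0.03 of `exp(-2 pi^2 sigma^2 f^2)` up to 1 cycle/mm
(the tests check this end to end); residual deviation is dominated by
the pixel aperture and the finite edge curvature, both of which shrink
with finer grids and larger inserts.

## NPS estimation

`tile_rois()` cuts the uniform region into 128 x 128 patches at 50%
overlap (defaults). Overlap buys ensemble size at the cost of
inter-patch covariance; the periodogram average remains unbiased, only
its effective number of degrees of freedom drops, and the scatter still
shrinks like 1/sqrt(ensemble) (a property the tests measure). Each
patch is detrended with a 2nd-order 2D polynomial (orders 0-2
available) so slow shading — residual bowtie shading, centring error,
contrast drift — does not masquerade as low-frequency noise power.

`estimate_nps2d()` uses the classical normalization
`NPS(u, v) = (dx dy / (Nx Ny)) mean |DFT(residual)|^2`, under which

    sum(NPS) * bin_area  ==  mean detrended-patch variance

is an exact Parseval identity (the tests require agreement to 1e-6
relative). This is what makes "the area under the NPS curve" equal the
noise SD squared, the property the overall-noise summary relies on.
`radial_average()` reports the 1D curve as the mean over annular
frequency bins (64 by default; the DC bin is excluded and reported
separately), and `noise_summary()` integrates the **2D** spectrum — not
the 1D curve — for the overall SD, avoiding the radial Jacobian
ambiguity entirely. The low/high band split defaults to 0.2 cycles/mm;
"low-frequency noise" has no canonical numeric definition, so the
cutoff is an explicit parameter rather than a hidden constant.

## The synthetic cohort

`cohort_spec()` encodes the paired clinical study conditions the
package targets: 36 patients, each reconstructed with both arms, with

* Gaussian objective-noise rows per anatomy (liver, upper fat, psoas,
  bladder, lower fat) at the published arm means/SDs (e.g. liver
  6.4 +/- 0.1 HU vs 9.5 +/- 0.1 HU);
* CNR rows drawn from their published Gaussians and **back-solved**
  into ROI means (`liver = psoas + CNR x upper-fat SD`), so the CNR
  computed downstream by `cohort_cnr()` recovers the generating row
  through the real formula rather than by construction. ROI baselines
  (psoas ~55 HU, bladder ~10 HU, fat ~-100 HU) are realistic values
  not fixed by any published table;
* 5-point ratings drawn per item from probability vectors whose
  expected values equal the published subjective scores and whose
  supports match the reported ranges (the smooth arm's noise scores are
  4-5 and its other scores 1-3; the sharp arm's scores are 3-5). The
  published rating SDs are not usable as generating parameters — values
  like 4.4 +/- 0.0 are impossible for integer scores — so the
  distributions are pinned by mean and support instead;
* two reviewers per rating, the second repeating the first with
  probability 0.8 (else redrawing), which leaves expected scores
  unchanged and produces the high (kappa ~0.9) agreement typical of
  such panels;
* a paired correlation (default 0.5) between arms for the continuous
  draws — the same patient is measured twice, so independence would be
  unrealistic; the liver's 3 hepatic ROIs are jittered around the
  patient's draw and aggregated downstream by their arithmetic mean
  (whether published liver noise averages the 3 ROI SDs or pools
  variances is unstated; the mean is the declared choice).

What the generator does **not** emulate: body-size-dependent noise,
inter-anatomy correlations beyond the shared pairing factor, missing
data, or reader drift. Passing tests therefore validate the estimator
and testing machinery, not the clinical claims themselves.

`generate_reference_group()` supplies the routine-protocol reference
cohort (n = 101, weight 57.3 +/- 14.4 kg, BMI 21.9 +/- 4.5 kg/m^2) for
the Welch body-size comparison.

## Statistics and reporting

`compare_arms()` produces the 14-row comparison table: 5 objective-noise
anatomies and 2 CNR sites by paired t-test, 7 subjective items by
Wilcoxon signed-rank. Raw two-sided p-values are reported without
multiplicity correction, matching the reporting convention of the study
design this mirrors. Subjective scores are averaged over the two
reviewers per patient by default (`rating_mode = "per_reviewer"` keeps
each reviewer as a pair instead; the underlying convention is unstated
in such reports, so both are supported).

The Wilcoxon implementation is in-package because its branching is part
of the contract: zero differences dropped (Pratt handling available),
mid-ranks for ties, an exact two-sided p by convolution over the rank
polynomial when there are at most 20 nonzero differences and no ties
(equivalent to enumerating all 2^n sign patterns — the tests verify
this against a literal brute-force enumerator and against
`stats::wilcox.test`), and otherwise a normal approximation with tie
and continuity corrections. The t-tests delegate to `stats::t.test`
(Welch form for the unpaired case, since variance equality is never
asserted). `weighted_kappa()` defaults to linear weights; the weighting
behind published single-kappa summaries is typically unstated, so the
choice is recorded in the result's `method` field, and quadratic
weights are available.

`render_report()` writes the bundle: `table2.csv`, `stats.json`
(rows + kappa), per-curve CSVs, a score-distribution export and
optional PNG figures. CSV/JSON output is byte-deterministic for fixed
inputs.

## Numerical choices and problem sizes

Defaults chosen once, with their rationale:

* ESF bin width 0.1 pixel; annulus 8 pixels either side of the edge.
* Hann window on the LSF; baseline from the outer 10% tails.
* NPS patches 128 px at 50% overlap, detrend order 2, 64 radial bins,
  band cutoff 0.2 cycles/mm.
* Noise-field calibration by expected variance (filter gain normalized),
  so sample SD converges to `noise_sd` as the grid grows (within 3% on
  512^2 grids).
* Phantom grids in the test-suite and examples use 256-512 px rasters
  at the 1024-matrix spacing (350/1024 mm) with single or 20-slice
  stacks, and the statistical property checks use 1000 simulated null
  cohorts — sizes at which every Monte-Carlo tolerance above holds with
  wide margin while the whole suite runs in seconds.

## Limitations

The reconstruction emulation is a blur + stationary-texture model: no
projection-domain physics, no beam hardening or photon starvation, no
non-stationarity across the field of view, and no actual iterative or
network reconstruction. TTF is measured at a single intermediate
contrast (the acrylic-like +120 HU task); low-contrast and through-plane
behaviour are out of scope, as are detectability indices built on the
NPS. The clinical generator reproduces marginal row structure, not full
patient physiology; conclusions about real scanners require real
images.
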