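# ctiq — task-based CT image quality assessment

`ctiq` is an R package for quantitative image-quality analysis of CT
reconstructions, aimed at medical physicists and imaging scientists
comparing reconstruction algorithms (hybrid iterative, model-based
iterative, deep-learning) on phantom and clinical data. Non-linear
reconstructions defeat the classical MTF/SD summaries, so the package
implements the task-based measurement chain used in their place,
together with a fully synthetic test bench so every estimator can be
validated against known ground truth without scanner data.

## What it computes

**Task-based transfer function (TTF).** From an axial image of a
cylindrical insert: radially acquired and binned profiles across the
circular edge give the edge-spread function ESF(r); its derivative is
the line-spread function; the TTF is the normalized Fourier magnitude

    TTF(f) = |F{LSF}(f)| / |F{LSF}(0)|,   LSF(r) = d ESF(r) / dr

with f50/f10 summary frequencies. For a Gaussian PSF of scale sigma the
chain must return `TTF(f) = exp(-2 pi^2 sigma^2 f^2)` — the oracle the
test suite holds it to.

**Noise power spectrum (NPS).** From overlapping detrended patches of a
uniform region:

    NPS(u, v) = (dx dy / (Nx Ny)) < |DFT(residual)|^2 >

normalized so that the area under the NPS equals the pixel variance
(exact Parseval identity). Radially averaged 1D curves, an overall SD
(square root of the NPS integral) and low/high-band power fractions at
a configurable cutoff (default 0.2 cycles/mm) summarize the texture.

**Clinical ROI metrics.** Objective noise (mean ROI SD across patients;
the liver aggregates 3 hepatic ROIs), two CNRs —

    CNR_liver  = (HU_liver - HU_psoas)   / SD_upper_fat
    CNR_pelvis = (HU_organ - HU_bladder) / SD_lower_fat

— effective dose `E = DLP x k` (k = 0.015 mSv mGy^-1 cm^-1 for the
abdomen/pelvis) and weight-based contrast-material volume/rate
arithmetic.

**Two-arm statistics.** Paired t (noise, CNR), exact/approximate
Wilcoxon signed-rank (5-point ordinal ratings), Welch t (group body
size), weighted Cohen's kappa (inter-reviewer agreement), and a
14-row report table with CSV/JSON export.

**Synthetic ground truth.** Phantom rendering with area-fraction
antialiasing (`qa_phantom()` with the standard insert materials,
`abdomen_phantom()` as a 330 x 220 mm ellipse), reconstruction
emulation as Gaussian blur plus stationary correlated noise of chosen
radial spectral shape, an AEC noise-index mapping (SD defined at 5 mm
slices: thin-slice SD = NI sqrt(5/t)), and a paired 36-patient cohort
generator with known generating means for every reported row.

## Worked example

```r
library(ctiq)
g <- grid_geometry(512, pixel_spacing = 350 / 1024)   # 1024-matrix spacing

# emulated scans of a QA phantom for two reconstruction arms
mbir <- recon_mbir_like(noise_sd = 7)     # smooth, low-frequency texture
dlr  <- recon_dlr_like(noise_sd = 8.5)    # sharp, fine-grain texture
ph   <- phantom_spec("disk", c(80, 80), background_hu = 0,
                     inserts = list(insert_spec("acrylic", c(0, 0), 12.5, 120)))
scan_mbir <- simulate_scan(ph, mbir, 35, g, seed = 1, n_slices = 20)
scan_dlr  <- simulate_scan(ph, dlr,  35, g, seed = 2, n_slices = 20)

ttf_mbir <- estimate_ttf(scan_mbir, c(0, 0), 12.5, annulus = 6)
ttf_dlr  <- estimate_ttf(scan_dlr,  c(0, 0), 12.5, annulus = 6)
sprintf("f50 MBIR-like: %.3f  f50 DLR-like: %.3f cycles/mm",
        attr(ttf_mbir, "f50"), attr(ttf_dlr, "f50"))
#> f50 MBIR-like: 0.336  f50 DLR-like: 0.507 cycles/mm

# noise texture in the uniform abdomen phantom
body <- abdomen_phantom()
gb <- grid_geometry(512, fov_mm = 400)
mask <- body_mask(simulate_scan(body, mbir, 35, gb, seed = 3), body, margin = 20)
estimate_nps(simulate_scan(body, mbir, 35, gb, seed = 3), mask, roi_size = 64)$summary
#> <noise_summary> SD 6.85 HU; 70.5% of power below 0.2 cycles/mm
estimate_nps(simulate_scan(body, dlr, 35, gb, seed = 4), mask, roi_size = 64)$summary
#> <noise_summary> SD 8.51 HU; 8.3% of power below 0.2 cycles/mm
```

The sharp arm resolves better (higher f50) but carries more overall
noise; the smooth arm parks 70% of its noise power below 0.2 cycles/mm
— the coarse low-frequency texture radiologists dislike.

```r
# paired clinical comparison on a simulated cohort
co  <- generate_cohort(cohort_spec())     # 36 patients, both arms
cmp <- compare_arms(co)
head(as.data.frame(cmp)[, c("quantity", "group", "mean_a", "mean_b", "p_value")], 5)
#>    quantity           group mean_a mean_b  p_value
#> 1     liver objective_noise   6.42   9.50 8.66e-38
#> 2 upper_fat objective_noise   6.91   8.58 4.08e-05
#> 3     psoas objective_noise   6.21   9.06 2.42e-13
#> 4   bladder objective_noise   6.33   9.24 2.77e-12
#> 5 lower_fat objective_noise   7.25   9.04 1.57e-05
sprintf("inter-reviewer weighted kappa: %.2f", attr(cmp, "kappa")$statistic)
#> inter-reviewer weighted kappa: 0.90

round(effective_dose(243.2), 1)   # mean DLP 243.2 mGy cm -> mSv
#> 3.6
percent_reduction(312, 520)       # reduced vs routine iodine load
#> 40
```

Every comparison row is significant at p < 0.001 with means at the
generating values — the cohort generator and the analysis chain agree
end to end. `render_report(cmp, dir = "report")` writes the table,
JSON and curve exports.

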