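Package: ctiq
Title: Task-Based CT Image Quality Assessment with Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative CT image-quality assessment: task-based
    transfer function (TTF) estimation from circular-edge inserts via the
    radial edge-spread / line-spread / Fourier chain, noise-power-spectrum
    (NPS) estimation from uniform phantom regions with band-limited noise
    summaries, clinical region-of-interest metrics (objective noise,
    contrast-to-noise ratio, effective dose, contrast-material arithmetic),
    and the paired statistical comparison of two reconstruction arms.
    Includes a synthetic phantom and cohort generator that emulates
    reconstruction-dependent blur and correlated noise texture so every
    estimator can be validated end-to-end against known ground truth
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
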