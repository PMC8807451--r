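#' Noise-texture spectral shapes
#'
#' Radial noise-power-spectrum shape families used by the reconstruction
#' emulator: a low-frequency Gaussian lobe `exp(-f^2 / 2 s1^2)` plus a
#' band-pass lobe `f * exp(-f^2 / 2 s2^2)`, mixed with nonnegative weights.
#' These are texture emulations, not models of any vendor algorithm:
#' a low-pass-heavy mixture mimics the coarse "oil painting" texture of
#' model-based iterative reconstruction, a band-pass-heavy mixture the
#' finer grain of filtered-backprojection-like or deep-learning outputs.
#'
#' @param lowpass_weight,bandpass_weight nonnegative mixture weights.
#' @param lowpass_scale,bandpass_scale lobe scales in cycles/mm.
#' @return A function of radial frequency (cycles/mm) returning a
#'   nonnegative relative power density.
#' @export
nps_shape <- function(lowpass_weight = 1, lowpass_scale = 0.15,
                      bandpass_weight = 0, bandpass_scale = 0.35) {
  if (lowpass_weight < 0 || bandpass_weight < 0)
    stop("mixture weights must be nonnegative")
  if (lowpass_scale <= 0 || bandpass_scale <= 0)
    stop("lobe scales must be positive")
  force(lowpass_weight); force(bandpass_weight)
  function(f) {
    lowpass_weight * exp(-f^2 / (2 * lowpass_scale^2)) +
      bandpass_weight * f * exp(-f^2 / (2 * bandpass_scale^2))
  }
}

#' Reconstruction emulation model
#'
#' Describes how a reconstruction arm is emulated: an isotropic Gaussian
#' point-spread function of scale `blur_sigma` (mm) and a stationary noise
#' field with radial spectral shape `nps_shape` scaled to pixel standard
#' deviation `noise_sd` (HU) at the reference slice thickness.
#'
#' @param label arm label, e.g. `"MBIR-like"`.
#' @param blur_sigma Gaussian PSF scale in mm, `>= 0`.
#' @param nps_shape function of radial frequency (cycles/mm), nonnegative;
#'   see [nps_shape()].
#' @param noise_sd target pixel SD in HU, `>= 0`; `NA` defers to the
#'   noise-index mapping in [simulate_scan()].
#' @return An object of class `recon_model`.
#' @export
recon_model <- function(label, blur_sigma, nps_shape = ctiq::nps_shape(),
                        noise_sd = NA_real_) {
  if (blur_sigma < 0) stop("blur_sigma must be nonnegative")
  if (!is.function(nps_shape)) stop("nps_shape must be a function")
  if (!is.na(noise_sd) && noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(label = as.character(label), blur_sigma = blur_sigma,
                 nps_shape = nps_shape, noise_sd = noise_sd),
            class = "recon_model")
}

#' Preset reconstruction emulations
#'
#' Three ready-made [recon_model()]s spanning the textures compared in
#' low-dose abdominopelvic work: `recon_mbir_like()` is smooth and
#' low-frequency-heavy, `recon_dlr_like()` sharper with a band-pass
#' (finer-grain) texture, `recon_hir_like()` in between.
#'
#' @param noise_sd target pixel SD in HU (thin slice); `NA` defers to the
#'   noise-index mapping.
#' @return A [recon_model()].
#' @export
recon_mbir_like <- function(noise_sd = NA_real_) {
  recon_model("MBIR-like", blur_sigma = 0.55,
              nps_shape = nps_shape(1, 0.12, 0, 0.35), noise_sd = noise_sd)
}

#' @rdname recon_mbir_like
#' @export
recon_dlr_like <- function(noise_sd = NA_real_) {
  recon_model("DLR-like", blur_sigma = 0.35,
              nps_shape = nps_shape(0.1, 0.12, 1, 0.35), noise_sd = noise_sd)
}

#' @rdname recon_mbir_like
#' @export
recon_hir_like <- function(noise_sd = NA_real_) {
  recon_model("HIR-like", blur_sigma = 0.45,
              nps_shape = nps_shape(0.5, 0.15, 0.5, 0.30), noise_sd = noise_sd)
}

# Discrete separable Gaussian kernel convolution with replicate padding.
gauss_blur_matrix <- function(m, sigma_px) {
  if (sigma_px == 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[n], r))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m <- apply(m, 2L, pad_conv)
  t(apply(t(m), 2L, pad_conv))
}

#' Apply reconstruction blur
#'
#' Convolves the image with the model's isotropic Gaussian point-spread
#' function (scale in mm, converted to pixels via the grid spacing).
#' Replicate edge padding keeps the spatial mean of uniform fields exact.
#'
#' @param img an [image_grid()].
#' @param model a [recon_model()] (or a single sigma in mm).
#' @return A blurred [image_grid()].
#' @export
apply_recon_blur <- function(img, model) {
  stopifnot(inherits(img, "image_grid"))
  sigma <- if (inherits(model, "recon_model")) model$blur_sigma else model
  if (sigma < 0) stop("blur sigma must be nonnegative")
  if (sigma == 0) return(img)
  sig_px <- sigma / img$pixel_spacing
  px <- img$pixels
  if (length(dim(px)) == 3L) {
    for (s in seq_len(dim(px)[3])) px[, , s] <- gauss_blur_matrix(px[, , s], sig_px)
  } else {
    px <- gauss_blur_matrix(px, sig_px)
  }
  image_grid(px, img$pixel_spacing, img$slice_thickness, img$origin)
}

# Unnormalized DFT sample frequencies (cycles/mm), fftshift-free order.
fft_freq <- function(n, spacing) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) / (n * spacing)
  k
}

#' Synthesize a correlated noise field
#'
#' Draws a zero-mean stationary Gaussian random field whose 2D power
#' spectrum is proportional to the model's radial `nps_shape`, scaled so
#' the pixel variance equals `noise_sd^2` in expectation. Implemented by
#' spectral filtering of white Gaussian noise; the filter's mean-square
#' gain is normalized to one, so the variance calibration is exact in
#' expectation rather than per realization.
#'
#' @param model a [recon_model()]; `noise_sd` must be set (not `NA`).
#' @param grid a [grid_geometry()].
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param n_slices number of independent slices to draw.
#' @return An [image_grid()] (matrix for `n_slices = 1`, else a 3D array)
#'   with the seed recorded in attribute `"seed"`.
#' @export
synthesize_noise <- function(model, grid, seed, n_slices = 1L) {
  stopifnot(inherits(model, "recon_model"), inherits(grid, "grid_geometry"))
  sd_target <- model$noise_sd
  if (is.na(sd_target)) stop("model noise_sd is NA; set it or use simulate_scan()")
  n <- grid$n
  if (sd_target == 0) {
    out <- if (n_slices == 1L) matrix(0, n, n) else array(0, c(n, n, n_slices))
    img <- image_grid(out, grid$pixel_spacing, grid$slice_thickness)
    attr(img, "seed") <- seed
    return(img)
  }
  fx <- fft_freq(n, grid$pixel_spacing)
  fr <- sqrt(outer(fx^2, fx^2, `+`))
  h2 <- model$nps_shape(fr)
  if (any(h2 < 0) || any(!is.finite(h2)))
    stop("nps_shape must be finite and nonnegative")
  if (all(h2 == 0))
    stop("nps_shape is identically zero but noise_sd > 0")
  h <- sqrt(h2 / mean(h2))            # unit mean-square gain
  set.seed(as.integer(seed))
  draw_slice <- function() {
    w <- matrix(stats::rnorm(n * n), n, n)
    Re(stats::fft(stats::fft(w) * h, inverse = TRUE)) / (n * n) * sd_target
  }
  out <- if (n_slices == 1L) draw_slice() else {
    a <- array(0, c(n, n, n_slices))
    for (s in seq_len(n_slices)) a[, , s] <- draw_slice()
    a
  }
  img <- image_grid(out, grid$pixel_spacing, grid$slice_thickness)
  attr(img, "seed") <- seed
  img
}

#' Map an AEC noise index to thin-slice noise SD
#'
#' The automatic-exposure-control noise index is defined as the target CT
#' number SD at 5 mm slice thickness; averaging over slices scales the
#' variance inversely with thickness, so the thin-slice SD is
#' `noise_index * sqrt(5 / slice_thickness)`.
#'
#' @param noise_index AEC noise index in HU (SD at 5 mm), positive.
#' @param slice_thickness reconstructed slice thickness in mm.
#' @return Target pixel SD in HU at the given thickness.
#' @examples
#' noise_index_to_sd(35, 0.5)   # 35 * sqrt(10) ~ 110.7 HU
#' @export
noise_index_to_sd <- function(noise_index, slice_thickness = 0.5) {
  if (noise_index <= 0) stop("noise_index must be positive")
  noise_index * sqrt(5 / slice_thickness)
}

#' Simulate a reconstructed phantom scan
#'
#' Full emulation chain: render the phantom, blur with the model's PSF,
#' and add a correlated noise field. The noise SD is the model's
#' `noise_sd` if set, otherwise mapped from the AEC noise index via
#' [noise_index_to_sd()].
#'
#' @param spec a [phantom_spec()].
#' @param model a [recon_model()].
#' @param noise_index AEC noise index in HU (SD at 5 mm slice thickness).
#' @param grid a [grid_geometry()].
#' @param seed integer seed for the noise draw.
#' @param n_slices number of slices to simulate (same anatomy, independent
#'   noise).
#' @return An [image_grid()] with attributes `"seed"` and `"noise_sd"`.
#' @export
simulate_scan <- function(spec, model, noise_index, grid, seed,
                          n_slices = 1L) {
  sd_thin <- if (!is.na(model$noise_sd)) model$noise_sd else
    noise_index_to_sd(noise_index, grid$slice_thickness)
  clean <- apply_recon_blur(render_phantom(spec, grid), model)
  nz_model <- recon_model(model$label, 0, model$nps_shape, noise_sd = sd_thin)
  noise <- synthesize_noise(nz_model, grid, seed, n_slices)
  px <- if (n_slices == 1L) clean$pixels + noise$pixels else
    sweep(noise$pixels, c(1, 2), clean$pixels, `+`)
  img <- image_grid(px, grid$pixel_spacing, grid$slice_thickness)
  attr(img, "seed") <- seed
  attr(img, "noise_sd") <- sd_thin
  img
}
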