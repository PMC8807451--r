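#' Tile a region into overlapping square ROIs
#'
#' Deterministic raster tiling of the masked region into `roi_size` x
#' `roi_size` pixel patches with the requested overlap fraction; only
#' patches lying fully inside the mask are kept. Slice stacks contribute
#' their tiles independently.
#'
#' @param img an [image_grid()] (2D or 3D).
#' @param mask logical matrix marking usable pixels, or `NULL` for the
#'   whole image.
#' @param roi_size patch side in pixels.
#' @param overlap overlap fraction in `[0, 1)`; 0.5 means adjacent patches
#'   share half their width.
#' @param min_rois minimum acceptable number of patches.
#' @return List of numeric matrices (HU patches).
#' @export
tile_rois <- function(img, mask = NULL, roi_size = 128L, overlap = 0.5,
                      min_rois = 4L) {
  stopifnot(inherits(img, "image_grid"))
  px <- img$pixels
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  nr <- dim(px)[1]; nc <- dim(px)[2]
  roi_size <- as.integer(roi_size)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)")
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  step <- max(1L, as.integer(round(roi_size * (1 - overlap))))
  if (nr < roi_size || nc < roi_size) {
    starts_r <- integer(0); starts_c <- integer(0)
  } else {
    starts_r <- seq(1L, nr - roi_size + 1L, by = step)
    starts_c <- seq(1L, nc - roi_size + 1L, by = step)
  }
  rois <- list()
  for (s in seq_len(dim(px)[3])) {
    for (i in starts_r) for (j in starts_c) {
      rr <- i:(i + roi_size - 1L); cc <- j:(j + roi_size - 1L)
      if (all(mask[rr, cc]))
        rois[[length(rois) + 1L]] <- px[rr, cc, s]
    }
  }
  if (length(rois) < min_rois)
    stop(sprintf("only %d ROI(s) fit inside the mask; need >= %d",
                 length(rois), min_rois))
  rois
}

#' Interior mask of an elliptical phantom body
#'
#' Pixels at least `margin` mm inside the body outline of a
#' [phantom_spec()], on the raster of `img`.
#'
#' @param img an [image_grid()].
#' @param spec a [phantom_spec()].
#' @param margin inset from the outline in mm.
#' @return Logical matrix.
#' @export
body_mask <- function(img, spec, margin = 10) {
  px <- img$pixels
  if (length(dim(px)) == 3L) px <- px[, , 1]
  xs <- grid_axis(ncol(px), img$pixel_spacing)
  ys <- grid_axis(nrow(px), img$pixel_spacing)
  X <- matrix(xs, nrow(px), ncol(px), byrow = TRUE)
  Y <- matrix(ys, nrow(px), ncol(px))
  a <- spec$semi_axes[1] - margin
  b <- spec$semi_axes[2] - margin
  if (a <= 0 || b <= 0) stop("margin exceeds the body semi-axes")
  (X / a)^2 + (Y / b)^2 <= 1
}

#' Remove slowly varying structure from an ROI
#'
#' Subtracts the least-squares 2D polynomial of the given order (default
#' 2: constant, linear and quadratic terms) so that only the stochastic
#' noise component remains; the residual has zero mean by construction.
#'
#' @param roi numeric matrix, at least 16 x 16.
#' @param order polynomial order, 0, 1 or 2.
#' @return Residual matrix of the same size.
#' @export
detrend_roi <- function(roi, order = 2L) {
  if (nrow(roi) < 16L || ncol(roi) < 16L) stop("ROI must be at least 16 x 16")
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  x <- seq_len(ncol(roi)) - (ncol(roi) + 1) / 2
  y <- seq_len(nrow(roi)) - (nrow(roi) + 1) / 2
  X <- matrix(x, nrow(roi), ncol(roi), byrow = TRUE)
  Y <- matrix(y, nrow(roi), ncol(roi))
  basis <- switch(as.character(order),
    "0" = matrix(1, length(roi), 1L),
    "1" = cbind(1, as.numeric(X), as.numeric(Y)),
    "2" = cbind(1, as.numeric(X), as.numeric(Y),
                as.numeric(X)^2, as.numeric(X) * as.numeric(Y),
                as.numeric(Y)^2))
  fit <- stats::lm.fit(basis, as.numeric(roi))
  matrix(fit$residuals, nrow(roi), ncol(roi))
}

#' Ensemble 2D noise power spectrum
#'
#' Averaged periodogram over detrended ROIs:
#' `NPS(u, v) = (dx * dy / (Nx * Ny)) * mean |DFT(residual)|^2`, in units
#' HU^2 mm^2. With this normalization the sum of the spectrum times the
#' frequency-bin area equals the mean residual variance exactly
#' (Parseval), so the area under the NPS is the noise variance.
#'
#' @param rois list of equal-size numeric matrices (already detrended, or
#'   set `detrend` to an order to detrend here).
#' @param pixel_spacing pixel pitch in mm.
#' @param detrend `NULL` or a polynomial order passed to [detrend_roi()].
#' @return Object of class `nps2d`: list with `power` (matrix, DC at
#'   element \[1,1\], unshifted DFT order), `freq_x`, `freq_y` (cycles/mm),
#'   `pixel_spacing`, `n_rois`, `mean_variance`, `bin_area`.
#' @export
estimate_nps2d <- function(rois, pixel_spacing, detrend = 2L) {
  if (length(rois) < 4L) stop("need at least 4 ROIs")
  dims <- vapply(rois, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all ROIs must share one size")
  if (!is.null(detrend)) rois <- lapply(rois, detrend_roi, order = detrend)
  nr <- dims[1, 1]; nc <- dims[2, 1]
  acc <- matrix(0, nr, nc)
  varsum <- 0
  for (r in rois) {
    acc <- acc + Mod(stats::fft(r))^2
    varsum <- varsum + mean(r^2)     # residuals are zero-mean
  }
  acc <- acc / length(rois)
  power <- pixel_spacing^2 / (nr * nc) * acc
  structure(list(power = power,
                 freq_x = fft_freq(nc, pixel_spacing),
                 freq_y = fft_freq(nr, pixel_spacing),
                 pixel_spacing = pixel_spacing,
                 n_rois = length(rois),
                 mean_variance = varsum / length(rois),
                 bin_area = 1 / (nr * nc * pixel_spacing^2)),
            class = "nps2d")
}

#' @export
print.nps2d <- function(x, ...) {
  cat(sprintf("<nps2d> %d x %d bins from %d ROIs; integral = %.4g HU^2 (SD %.3g HU)\n",
              nrow(x$power), ncol(x$power), x$n_rois,
              sum(x$power) * x$bin_area, sqrt(sum(x$power) * x$bin_area)))
  invisible(x)
}

#' Radially averaged 1D NPS curve
#'
#' Mean of the 2D spectrum in annular radial-frequency bins from 0 to the
#' Nyquist frequency. The DC bin is excluded from the annuli and reported
#' in the `"dc"` attribute.
#'
#' @param nps2 an `nps2d` object.
#' @param n_bins number of radial bins (>= 8).
#' @return data.frame of class `nps_curve` with columns `radial_frequency`
#'   (cycles/mm, bin centres) and `power` (HU^2 mm^2).
#' @export
radial_average <- function(nps2, n_bins = 64L) {
  if (n_bins < 8L) stop("n_bins must be at least 8")
  fr <- sqrt(outer(nps2$freq_y^2, nps2$freq_x^2, `+`))
  nyq <- 1 / (2 * nps2$pixel_spacing)
  edges <- seq(0, nyq, length.out = n_bins + 1L)
  sel <- fr > 0 & fr <= nyq
  bin <- findInterval(fr[sel], edges, rightmost.closed = TRUE)
  pw <- tapply(nps2$power[sel], bin, mean)
  idx <- as.integer(names(pw))
  out <- data.frame(radial_frequency = (edges[idx] + edges[idx + 1L]) / 2,
                    power = as.numeric(pw))
  out <- out[order(out$radial_frequency), ]
  rownames(out) <- NULL
  class(out) <- c("nps_curve", "data.frame")
  attr(out, "dc") <- nps2$power[1, 1]
  out
}

#' Overall and band-limited noise summary
#'
#' Integrates the 2D NPS: `overall_sd` is the square root of the area
#' under the spectrum (i.e. the noise SD in HU), and the low/high band
#' fractions split the total power at a radial-frequency cutoff.
#'
#' @param nps2 an `nps2d` object.
#' @param cutoff band cutoff in cycles/mm, in (0, Nyquist).
#' @return List of class `noise_summary`: `overall_sd`, `low_band_power`,
#'   `high_band_power` (fractions summing to 1), `cutoff`.
#' @export
noise_summary <- function(nps2, cutoff = 0.2) {
  nyq <- 1 / (2 * nps2$pixel_spacing)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (cutoff >= nyq) stop("cutoff must lie below the Nyquist frequency")
  fr <- sqrt(outer(nps2$freq_y^2, nps2$freq_x^2, `+`))
  total <- sum(nps2$power)
  low <- sum(nps2$power[fr < cutoff])
  overall_sd <- sqrt(total * nps2$bin_area)
  structure(list(overall_sd = overall_sd,
                 low_band_power = if (total > 0) low / total else 0,
                 high_band_power = if (total > 0) 1 - low / total else 0,
                 cutoff = cutoff),
            class = "noise_summary")
}

#' @export
print.noise_summary <- function(x, ...) {
  cat(sprintf("<noise_summary> SD %.3g HU; %.1f%% of power below %.3g cycles/mm\n",
              x$overall_sd, 100 * x$low_band_power, x$cutoff))
  invisible(x)
}

#' One-call NPS estimation from a uniform-region image
#'
#' Convenience chain: [tile_rois()] -> [detrend_roi()] ->
#' [estimate_nps2d()] -> [radial_average()] and [noise_summary()].
#'
#' @inheritParams tile_rois
#' @inheritParams noise_summary
#' @param detrend polynomial order for [detrend_roi()].
#' @param n_bins radial bins for [radial_average()].
#' @return List with `nps2d`, `curve`, `summary`.
#' @export
estimate_nps <- function(img, mask = NULL, roi_size = 128L, overlap = 0.5,
                         detrend = 2L, n_bins = 64L, cutoff = 0.2) {
  rois <- tile_rois(img, mask, roi_size, overlap)
  nps2 <- estimate_nps2d(rois, img$pixel_spacing, detrend = detrend)
  list(nps2d = nps2, curve = radial_average(nps2, n_bins),
       summary = noise_summary(nps2, cutoff))
}
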