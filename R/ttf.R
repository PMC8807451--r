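#' Locate a circular insert to subpixel precision
#'
#' Finds the centre of a cylindrical insert near an approximate position:
#' pixels within 1.3x the nominal radius are thresholded at the midpoint
#' between the local inside and outside medians, and the centre is the
#' contrast-weighted centroid of the thresholded disk, refined once from
#' the first estimate.
#'
#' @param img an [image_grid()] (2D, or the first slice of a stack is used).
#' @param approx_center length-2 numeric, approximate centre in mm.
#' @param approx_radius nominal insert radius in mm.
#' @param min_contrast minimum |inside - outside| HU difference required
#'   to accept a detection.
#' @return Length-2 numeric centre (mm) with attributes `"contrast"` and
#'   `"residual"` (shift applied in the refinement pass, mm).
#' @export
estimate_center <- function(img, approx_center, approx_radius,
                            min_contrast = 20) {
  stopifnot(inherits(img, "image_grid"))
  px <- img$pixels
  if (length(dim(px)) == 3L) px <- px[, , 1]
  sp <- img$pixel_spacing
  xs <- grid_axis(ncol(px), sp)
  ys <- grid_axis(nrow(px), sp)
  centroid_pass <- function(center) {
    dx <- matrix(xs - center[1], nrow(px), ncol(px), byrow = TRUE)
    dy <- matrix(ys - center[2], nrow(px), ncol(px))
    r <- sqrt(dx^2 + dy^2)
    inside <- r < 0.5 * approx_radius
    ring <- r > 1.5 * approx_radius & r < 2.5 * approx_radius
    if (!any(inside) || !any(ring))
      stop("no usable region near approx_center")
    hu_in <- stats::median(px[inside])
    hu_out <- stats::median(px[ring])
    contrast <- hu_in - hu_out
    if (abs(contrast) < min_contrast)
      stop(sprintf("no insert detected: |contrast| = %.1f HU below %.1f HU",
                   abs(contrast), min_contrast))
    thr <- (hu_in + hu_out) / 2
    sel <- if (contrast > 0) px > thr else px < thr
    sel <- sel & r < 1.3 * approx_radius
    if (!any(sel)) stop("no connected region near approx_center")
    w <- abs(px[sel] - hu_out)
    cx <- sum((dx[sel] + center[1]) * w) / sum(w)
    cy <- sum((dy[sel] + center[2]) * w) / sum(w)
    list(center = c(cx, cy), contrast = contrast)
  }
  p1 <- centroid_pass(approx_center)
  p2 <- centroid_pass(p1$center)
  out <- p2$center
  attr(out, "contrast") <- p2$contrast
  attr(out, "residual") <- sqrt(sum((p2$center - p1$center)^2))
  out
}

#' Radially binned edge-spread function
#'
#' Every pixel of every slice whose distance to the insert centre falls
#' within `annulus` of the nominal radius contributes the pair
#' (distance - nominal_radius, HU); pairs are averaged in distance bins of
#' width `bin_width`. Oversampling comes from the circular edge: pixel
#' centres sample the signed edge distance almost continuously, so bins
#' much narrower than a pixel stay populated. Slice stacks are pooled at
#' the sample level.
#'
#' @param img an [image_grid()] (2D or 3D).
#' @param center insert centre (mm), e.g. from [estimate_center()].
#' @param nominal_radius insert radius in mm.
#' @param bin_width bin width in mm; default 0.1 pixel.
#' @param annulus half-width of the radial window around the edge, mm.
#' @return data.frame of class `esf_curve` with columns `distance` (mm,
#'   bin centres, increasing), `value` (HU), `n` (samples per bin); bins
#'   with no samples are dropped.
#' @export
extract_radial_esf <- function(img, center, nominal_radius,
                               bin_width = 0.1 * img$pixel_spacing,
                               annulus = 8 * img$pixel_spacing) {
  stopifnot(inherits(img, "image_grid"))
  px <- img$pixels
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  sp <- img$pixel_spacing
  xs <- grid_axis(dim(px)[2], sp)
  ys <- grid_axis(dim(px)[1], sp)
  dx <- matrix(xs - center[1], dim(px)[1], dim(px)[2], byrow = TRUE)
  dy <- matrix(ys - center[2], dim(px)[1], dim(px)[2])
  d <- sqrt(dx^2 + dy^2) - nominal_radius
  keep <- abs(d) <= annulus
  if (!any(keep)) stop("annulus lies outside the image")
  # the full ring must fit inside the grid for an unbiased radial average
  border <- min(max(xs) - center[1], center[1] - min(xs),
                max(ys) - center[2], center[2] - min(ys)) + sp / 2
  if (border < nominal_radius + annulus)
    stop("annulus extends outside the image")
  dvec <- rep(d[keep], dim(px)[3])
  vvec <- as.numeric(apply(px, 3L, function(s) s[keep]))
  edges <- seq(-annulus, annulus + bin_width, by = bin_width)
  bin <- findInterval(dvec, edges, rightmost.closed = TRUE)
  value <- tapply(vvec, bin, mean)
  count <- tapply(vvec, bin, length)
  idx <- as.integer(names(value))
  out <- data.frame(distance = edges[idx] + bin_width / 2,
                    value = as.numeric(value), n = as.integer(count))
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  class(out) <- c("esf_curve", "data.frame")
  attr(out, "bin_width") <- bin_width
  out
}

#' Differentiate an edge-spread function
#'
#' Resamples the ESF onto a uniform grid (linear interpolation across any
#' dropped bins), optionally applies Savitzky-Golay smoothing, and takes
#' the central-difference derivative. The LSF is oriented so its area is
#' positive; the area approximates the edge's plateau contrast.
#'
#' @param esf an `esf_curve` from [extract_radial_esf()].
#' @param smooth `NULL` (default, no smoothing) or a list
#'   `list(window = odd integer, order = poly order)` for Savitzky-Golay
#'   pre-smoothing of the ESF.
#' @return data.frame of class `lsf_curve` with columns `position` (mm)
#'   and `value` (HU/mm); attribute `"area"` holds the integral.
#' @export
esf_to_lsf <- function(esf, smooth = NULL) {
  if (nrow(esf) < 8L) stop("need at least 8 ESF bins to differentiate")
  h <- attr(esf, "bin_width")
  if (is.null(h)) h <- stats::median(diff(esf$distance))
  grid <- seq(min(esf$distance), max(esf$distance), by = h)
  v <- stats::approx(esf$distance, esf$value, xout = grid, rule = 2)$y
  if (!is.null(smooth)) {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("signal package required for smoothing")
    v <- signal::sgolayfilt(v, p = smooth$order, n = smooth$window)
  }
  n <- length(v)
  deriv <- numeric(n)
  deriv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
  deriv[1] <- (v[2] - v[1]) / h
  deriv[n] <- (v[n] - v[n - 1]) / h
  area <- sum(deriv) * h
  if (area < 0) { deriv <- -deriv; area <- -area }
  out <- data.frame(position = grid, value = deriv)
  class(out) <- c("lsf_curve", "data.frame")
  attr(out, "area") <- area
  attr(out, "spacing") <- h
  out
}

#' Fourier transform of the line-spread function
#'
#' Subtracts the tail baseline (mean of the outer 10% of samples on each
#' side), applies a Hann window centred on the LSF peak, and returns the
#' normalized DFT magnitude: the task-based transfer function, with
#' modulation exactly 1 at zero frequency.
#'
#' @param lsf an `lsf_curve` from [esf_to_lsf()].
#' @param window `"hann"` (default) or `"none"`.
#' @return data.frame of class `ttf_curve` with columns `frequency`
#'   (cycles/mm, 0 to Nyquist) and `modulation`.
#' @export
lsf_to_ttf <- function(lsf, window = c("hann", "none")) {
  window <- match.arg(window)
  v <- lsf$value
  h <- attr(lsf, "spacing")
  if (is.null(h)) h <- stats::median(diff(lsf$position))
  n <- length(v)
  ntail <- max(1L, floor(0.1 * n))
  v <- v - mean(c(v[seq_len(ntail)], v[seq(n - ntail + 1L, n)]))
  if (window == "hann") {
    peak <- which.max(abs(v))
    half <- max(peak - 1L, n - peak)
    w <- 0.5 * (1 + cos(pi * (seq_len(n) - peak) / half))
    v <- v * w
  }
  if (sum(v) == 0) stop("zero-area LSF cannot be normalized")
  mod <- Mod(stats::fft(v))
  if (mod[1] == 0) stop("zero-area LSF cannot be normalized")
  mod <- mod / mod[1]
  nk <- floor(n / 2) + 1L
  out <- data.frame(frequency = (seq_len(nk) - 1L) / (n * h),
                    modulation = mod[seq_len(nk)])
  class(out) <- c("ttf_curve", "data.frame")
  out
}

#' Frequency at a modulation fraction
#'
#' Linear interpolation of the first downward crossing of the TTF through
#' `fraction` (e.g. 0.5 for the 50% frequency f50).
#'
#' @param curve a `ttf_curve`.
#' @param fraction target modulation in (0, 1).
#' @return Frequency in cycles/mm.
#' @export
ttf_at_fraction <- function(curve, fraction) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  m <- curve$modulation
  f <- curve$frequency
  below <- which(m < fraction)
  if (length(below) == 0L)
    stop("curve never crosses the requested fraction")
  i <- below[1]
  if (i == 1L) return(f[1])
  f[i - 1] + (fraction - m[i - 1]) * (f[i] - f[i - 1]) / (m[i] - m[i - 1])
}

#' One-call TTF estimation from an insert image
#'
#' Convenience chain: [estimate_center()] -> [extract_radial_esf()] ->
#' [esf_to_lsf()] -> [lsf_to_ttf()].
#'
#' @inheritParams estimate_center
#' @inheritParams extract_radial_esf
#' @param smooth passed to [esf_to_lsf()].
#' @return A `ttf_curve` with attributes `esf`, `lsf`, `center`,
#'   `contrast`, `f50` and `f10` (the latter `NA` if never crossed).
#' @export
estimate_ttf <- function(img, approx_center, approx_radius,
                         bin_width = 0.1 * img$pixel_spacing,
                         annulus = 8 * img$pixel_spacing, smooth = NULL) {
  ctr <- estimate_center(img, approx_center, approx_radius)
  esf <- extract_radial_esf(img, ctr, approx_radius, bin_width, annulus)
  lsf <- esf_to_lsf(esf, smooth)
  ttf <- lsf_to_ttf(lsf)
  attr(ttf, "esf") <- esf
  attr(ttf, "lsf") <- lsf
  attr(ttf, "center") <- as.numeric(ctr)
  attr(ttf, "contrast") <- attr(lsf, "area")
  attr(ttf, "f50") <- tryCatch(ttf_at_fraction(ttf, 0.5),
                               error = function(e) NA_real_)
  attr(ttf, "f10") <- tryCatch(ttf_at_fraction(ttf, 0.1),
                               error = function(e) NA_real_)
  ttf
}
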