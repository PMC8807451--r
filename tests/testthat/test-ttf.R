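test_that("insert centres are recovered to subpixel precision", {
  fx <- acrylic_disk(n = 128)
  sp <- fx$grid$pixel_spacing
  ctr <- estimate_center(fx$img, c(0, 0), fx$radius)
  expect_lt(sqrt(sum(ctr^2)), 0.05 * sp)
  expect_equal(attr(ctr, "contrast"), 120, tolerance = 0.02)

  # shifted disk: recovered within 0.1 px of the true shift
  shift <- c(1.3, -0.7) * sp
  body_r <- fx$spec$semi_axes[1]
  spec <- phantom_spec("disk", c(body_r, body_r), background_hu = 0,
                       inserts = list(insert_spec("a", shift, fx$radius, 120)),
                       outside_hu = 0)
  img <- render_phantom(spec, fx$grid)
  ctr2 <- estimate_center(img, c(0, 0), fx$radius)
  expect_lt(sqrt(sum((ctr2 - shift)^2)), 0.1 * sp)

  # pure noise: no insert to detect
  set.seed(1)
  noise <- image_grid(matrix(rnorm(128^2, 0, 5), 128, 128), sp)
  expect_error(estimate_center(noise, c(0, 0), fx$radius), "contrast")
})

test_that("radial ESF of a sharp disk is a two-plateau step", {
  fx <- acrylic_disk(n = 128)
  esf <- extract_radial_esf(fx$img, c(0, 0), fx$radius, annulus = 5)
  inner <- esf$value[esf$distance < -1]
  outer <- esf$value[esf$distance > 1]
  expect_equal(mean(inner), 120, tolerance = 1e-6)
  expect_equal(mean(outer), 0, tolerance = 1e-6)
  expect_true(all(diff(esf$distance) > 0))
  expect_true(all(esf$n >= 1L))
  expect_error(extract_radial_esf(fx$img, c(0, 0), fx$radius, annulus = 100),
               "outside")
})

test_that("blurred-disk ESF matches the scaled normal CDF", {
  # gently curved edge (radius >> sigma) so the straight-edge closed form
  # applies; the rendered edge carries the pixel-aperture box prefilter,
  # so the effective scale is sqrt(sigma^2 + spacing^2 / 12)
  fx <- acrylic_disk(radius = 30)
  sigma <- 0.5
  sigma_eff <- sqrt(sigma^2 + fx$grid$pixel_spacing^2 / 12)
  bl <- apply_recon_blur(fx$img, sigma)
  esf <- extract_radial_esf(bl, c(0, 0), fx$radius, annulus = 5)
  expected <- 120 * pnorm(-esf$distance / sigma_eff)
  expect_lt(max(abs(esf$value - expected)), 0.01 * 120)
  # plateau contrast recovery (acrylic on water = 120 HU)
  contrast <- mean(esf$value[esf$distance < -3]) -
    mean(esf$value[esf$distance > 3])
  expect_equal(contrast, 120, tolerance = 0.01)
})

test_that("differentiating the ESF yields the matching LSF", {
  # step ESF -> single-bin impulse of area = contrast
  d <- seq(-2, 2, by = 0.1)
  step <- structure(data.frame(distance = d, value = ifelse(d < 0, 120, 0),
                               n = 1L),
                    class = c("esf_curve", "data.frame"), bin_width = 0.1)
  lsf <- esf_to_lsf(step)
  expect_equal(attr(lsf, "area"), 120, tolerance = 0.01)
  expect_lt(sum(lsf$value > max(lsf$value) / 2), 3)
  # normal-CDF ESF -> Gaussian LSF peaked at the edge
  sigma <- 0.4
  esf <- structure(data.frame(distance = d, value = 120 * pnorm(-d / sigma),
                              n = 1L),
                   class = c("esf_curve", "data.frame"), bin_width = 0.1)
  lsf2 <- esf_to_lsf(esf)
  gauss <- 120 * dnorm(lsf2$position / sigma) / sigma
  expect_lt(max(abs(lsf2$value - gauss)), 0.02 * max(gauss))
  expect_lt(abs(lsf2$position[which.max(lsf2$value)]), 0.1 + 1e-12)
  # flat ESF -> zero LSF; short ESF -> error
  flat <- structure(data.frame(distance = d, value = 50, n = 1L),
                    class = c("esf_curve", "data.frame"), bin_width = 0.1)
  expect_true(all(esf_to_lsf(flat)$value == 0))
  expect_error(esf_to_lsf(step[1:5, ]), "8")
})

test_that("optional Savitzky-Golay smoothing keeps the LSF area", {
  set.seed(13)
  d <- seq(-3, 3, by = 0.05)
  esf <- structure(data.frame(distance = d,
                              value = 120 * pnorm(-d / 0.5) + rnorm(length(d), 0, 1),
                              n = 1L),
                   class = c("esf_curve", "data.frame"), bin_width = 0.05)
  raw <- esf_to_lsf(esf)
  sm <- esf_to_lsf(esf, smooth = list(window = 11L, order = 2L))
  expect_equal(attr(sm, "area"), 120, tolerance = 0.05)
  # smoothing reduces the high-frequency jitter of the derivative
  expect_lt(sd(diff(sm$value)), sd(diff(raw$value)))
})

test_that("the TTF of a Gaussian LSF follows the closed form", {
  # impulse LSF -> flat modulation
  pos <- seq(-5, 5, by = 0.05)
  imp <- structure(data.frame(position = pos,
                              value = ifelse(abs(pos) < 1e-9, 1 / 0.05, 0)),
                   class = c("lsf_curve", "data.frame"), spacing = 0.05)
  ttf_i <- lsf_to_ttf(imp, window = "none")
  expect_true(all(abs(ttf_i$modulation - 1) < 1e-9))
  # Gaussian LSF, sigma = 0.5 mm: modulation = exp(-2 pi^2 sigma^2 f^2)
  sigma <- 0.5
  g <- structure(data.frame(position = pos, value = dnorm(pos / sigma) / sigma),
                 class = c("lsf_curve", "data.frame"), spacing = 0.05)
  ttf <- lsf_to_ttf(g, window = "none")
  expect_equal(ttf$modulation[1], 1)
  sel <- ttf$frequency <= 1.5
  expect_lt(max(abs(ttf$modulation[sel] -
                      exp(-2 * pi^2 * sigma^2 * ttf$frequency[sel]^2))), 0.01)
  # f at 0.3 cycles/mm ~ exp(-0.444)
  m03 <- approx(ttf$frequency, ttf$modulation, xout = 0.3)$y
  expect_equal(m03, exp(-2 * pi^2 * 0.25 * 0.09), tolerance = 0.01)
  # zero-area LSF cannot be normalized
  z <- structure(data.frame(position = pos, value = 0 * pos),
                 class = c("lsf_curve", "data.frame"), spacing = 0.05)
  expect_error(lsf_to_ttf(z), "zero-area")
})

test_that("modulation fractions interpolate the first downward crossing", {
  sigma <- 0.5
  f <- seq(0, 2, by = 0.01)
  curve <- structure(data.frame(frequency = f,
                                modulation = exp(-2 * pi^2 * sigma^2 * f^2)),
                     class = c("ttf_curve", "data.frame"))
  f50 <- ttf_at_fraction(curve, 0.5)
  expect_equal(f50, sqrt(log(2) / (2 * pi^2 * sigma^2)), tolerance = 1e-3)
  expect_error(ttf_at_fraction(curve, 1.0), "between")
  expect_error(ttf_at_fraction(curve[curve$frequency <= 1, ], 0.001), "cross")
  # coarse vs fine sampling agree within one coarse bin
  coarse <- curve[seq(1, nrow(curve), by = 10), ]
  expect_lt(abs(ttf_at_fraction(coarse, 0.5) - f50), 0.1)
})

test_that("the estimated TTF matches the Gaussian oracle end to end", {
  fx <- acrylic_disk()
  sigma <- 0.5
  bl <- apply_recon_blur(fx$img, sigma)
  ttf <- estimate_ttf(bl, c(0, 0), fx$radius, annulus = 6)
  expect_equal(ttf$modulation[1], 1)
  sel <- ttf$frequency <= 1
  oracle <- exp(-2 * pi^2 * sigma^2 * ttf$frequency[sel]^2)
  expect_lt(max(abs(ttf$modulation[sel] - oracle)), 0.03)
  expect_equal(attr(ttf, "f50"), sqrt(log(2) / (2 * pi^2 * sigma^2)),
               tolerance = 0.02)
  expect_equal(attr(ttf, "contrast"), 120, tolerance = 0.02)
})

test_that("noisy multi-slice TTF stays near the oracle and orders blurs", {
  fx <- acrylic_disk()
  sigma <- 0.5
  spec <- fx$spec
  model <- recon_model("m", sigma, nps_shape(1, 1e6), noise_sd = 5)
  img <- simulate_scan(spec, model, 35, fx$grid, seed = 17, n_slices = 20)
  ttf <- estimate_ttf(img, c(0, 0), fx$radius, annulus = 6)
  sel <- ttf$frequency <= 1
  oracle <- exp(-2 * pi^2 * sigma^2 * ttf$frequency[sel]^2)
  expect_lt(max(abs(ttf$modulation[sel] - oracle)), 0.08)

  # larger blur never increases f50 (one-bin tolerance)
  f50 <- vapply(c(0.3, 0.45, 0.6), function(s) {
    b <- apply_recon_blur(fx$img, s)
    attr(estimate_ttf(b, c(0, 0), fx$radius, annulus = 6), "f50")
  }, numeric(1))
  expect_true(all(diff(f50) < 1e-6))
})
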