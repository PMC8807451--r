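test_that("rendered phantoms place material HU values correctly", {
  fx <- acrylic_disk()
  n <- fx$grid$n
  ctr <- (n + 1) / 2
  # pixel nearest the insert centre carries the acrylic HU
  expect_equal(fx$img$pixels[round(ctr), round(ctr)], 120)
  # a pixel well inside the background (inside body, outside insert)
  off <- round(ctr + 25 / fx$grid$pixel_spacing)
  expect_equal(fx$img$pixels[round(ctr), off], 0)
  # zero inserts, zero background: all body pixels are 0
  flat <- phantom_spec("disk", c(40, 40), background_hu = 0, outside_hu = 0)
  img0 <- render_phantom(flat, fx$grid)
  expect_true(all(img0$pixels == 0))
})

test_that("pixel-centre rendering matches a brute-force containment oracle", {
  radius <- 5
  spec <- phantom_spec("disk", c(20, 20), background_hu = 0,
                       inserts = list(insert_spec("x", c(1.7, -2.3),
                                                  radius, 120)),
                       outside_hu = 0)
  g <- grid_geometry(100, pixel_spacing = 0.5)
  img <- render_phantom(spec, g, antialias = FALSE)
  # oracle: count pixel centres inside the disk directly
  ax <- (seq_len(100) - 50.5) * 0.5
  inside <- outer(ax - (-2.3), ax - 1.7,
                  function(y, x) sqrt(x^2 + y^2)) < radius
  expect_identical(sum(img$pixels >= 120), sum(inside))
  # antialiased mode conserves the disk area to a fraction of a pixel ring
  imga <- render_phantom(spec, g, antialias = TRUE)
  area_px <- sum(imga$pixels / 120)
  expect_equal(area_px * 0.5^2, pi * radius^2, tolerance = 0.01)
})

test_that("insert geometry is validated", {
  expect_error(insert_spec("bad", c(0, 0), -1, 100), "radius")
  expect_error(insert_spec("bad", c(0, 0), 5, 5000), "hu_value")
  expect_error(
    phantom_spec("disk", c(20, 20),
                 inserts = list(insert_spec("out", c(18, 0), 5, 120))),
    "outside")
  expect_error(render_phantom(qa_phantom(), grid_geometry(32, fov_mm = 50)),
               "cover")
})

test_that("reconstruction blur is a mean-preserving Gaussian PSF", {
  fx <- acrylic_disk(n = 128)
  expect_identical(apply_recon_blur(fx$img, 0)$pixels, fx$img$pixels)
  # uniform image unchanged (to numerical precision)
  u <- image_grid(matrix(37, 64, 64), 0.5)
  expect_equal(apply_recon_blur(u, 1.0)$pixels, u$pixels, tolerance = 1e-12)
  # spatial mean preserved to < 1e-6 relative
  b <- apply_recon_blur(fx$img, 0.5)
  expect_equal(mean(b$pixels), mean(fx$img$pixels), tolerance = 1e-6)
  # Gaussian edge response: one-dimensional step of 120 HU, sigma 0.5 mm
  step <- image_grid(matrix(rep(c(rep(0, 32), rep(120, 32)), times = 64),
                            64, 64, byrow = TRUE), 0.5)
  bs <- apply_recon_blur(step, 0.5)
  # profile value 0.5 mm inside the high side of the edge = 120 * pnorm(1)
  edge_col <- 32.5                       # edge lies between columns 32 and 33
  prof <- bs$pixels[32, ]
  v <- approx((seq_len(64) - edge_col) * 0.5, prof, xout = 0.5)$y
  expect_equal(v, 120 * pnorm(1), tolerance = 120 * 0.01)
})

test_that("synthesized noise is calibrated, reproducible and validated", {
  g <- grid_geometry(256, pixel_spacing = 0.5)
  expect_true(all(synthesize_noise(white_model(0), g, 1)$pixels == 0))
  nz <- synthesize_noise(white_model(10), g, 7)
  expect_lt(abs(sd(nz$pixels) - 10) / 10, 0.03)
  expect_lt(abs(mean(nz$pixels)), 0.5)
  # determinism: same seed, same field
  nz2 <- synthesize_noise(white_model(10), g, 7)
  expect_identical(nz$pixels, nz2$pixels)
  expect_false(identical(nz$pixels, synthesize_noise(white_model(10), g, 8)$pixels))
  # all-zero shape with positive SD is rejected
  zero_shape <- recon_model("z", 0, function(f) 0 * f, noise_sd = 5)
  expect_error(synthesize_noise(zero_shape, g, 1), "zero")
})

test_that("low-pass synthesized noise concentrates below the pass cutoff", {
  g <- grid_geometry(256, pixel_spacing = 0.5)
  nz <- synthesize_noise(low_pass_model(8), g, 3)
  s <- estimate_nps(nz, roi_size = 64)$summary
  expect_gt(s$low_band_power, 0.5)
})

test_that("scan simulation maps the AEC noise index to thin-slice SD", {
  expect_equal(noise_index_to_sd(35, 0.5), 35 * sqrt(10))
  expect_equal(noise_index_to_sd(35, 5), 35)
  # doubling the index quadruples the target variance
  expect_equal(noise_index_to_sd(70, 0.5)^2 / noise_index_to_sd(35, 0.5)^2, 4)
  expect_error(noise_index_to_sd(0), "positive")

  spec <- phantom_spec("disk", c(30, 30), background_hu = 0, outside_hu = 0)
  g <- grid_geometry(128, pixel_spacing = 0.5)
  img <- simulate_scan(spec, white_model(NA), 35, g, seed = 2)
  expect_equal(attr(img, "noise_sd"), 35 * sqrt(10))
  img_b <- simulate_scan(spec, white_model(NA), 35, g, seed = 2)
  expect_identical(img$pixels, img_b$pixels)
  # explicit model noise_sd overrides the mapping
  img_o <- simulate_scan(spec, white_model(12), 35, g, seed = 2)
  expect_equal(attr(img_o, "noise_sd"), 12)
})

test_that("cohort draws recover their generating parameters", {
  cs <- cohort_spec(n_patients = 10000L, seed = 31L)
  co <- generate_cohort(cs)
  liver <- objective_noise(co$measurements, "liver", "MBIR")
  expect_equal(liver$mean, 6.4, tolerance = 0.01 / 6.4)
  # high paired correlation survives into the samples
  cs2 <- cohort_spec(n_patients = 1000L, paired_correlation = 0.99, seed = 5L)
  co2 <- generate_cohort(cs2)
  va <- objective_noise(co2$measurements, "psoas", "MBIR")$values
  vb <- objective_noise(co2$measurements, "psoas", "DLR")$values
  expect_gt(cor(va, vb), 0.9)
  # degenerate rating distribution pins every score
  probs <- default_rating_probs()
  for (arm in c("a", "b"))
    for (item in names(probs[[arm]]))
      probs[[arm]][[item]] <- c(0, 0, 1, 0, 0)
  co3 <- generate_cohort(cohort_spec(n_patients = 20L, ratings = probs,
                                     seed = 9L))
  expect_true(all(co3$ratings$score == 3L))
  # determinism
  expect_identical(generate_cohort(cohort_spec(seed = 4L)),
                   generate_cohort(cohort_spec(seed = 4L)))
})

test_that("cohort specs validate their probability vectors", {
  probs <- default_rating_probs()
  probs$a$noise_liver <- c(0.5, 0.5, 0.5, 0, 0)
  expect_error(cohort_spec(ratings = probs), "simplex")
  expect_error(cohort_spec(paired_correlation = 1), "correlation")
})

test_that("cohort tables round-trip through CSV", {
  co <- generate_cohort(cohort_spec(n_patients = 5L, seed = 2L))
  dir <- withr::local_tempdir()
  paths <- write_cohort_csv(co, dir)
  expect_true(all(file.exists(paths)))
  m <- read.csv(file.path(dir, "measurements.csv"))
  expect_equal(nrow(m), nrow(co$measurements))
  expect_equal(m$sd_hu, co$measurements$sd_hu, tolerance = 1e-12)
})
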