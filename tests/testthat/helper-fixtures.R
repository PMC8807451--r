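# Shared synthetic fixtures, built in code at test time.

# acrylic-contrast disk (120 HU on water) on the high-resolution raster,
# small enough for fast blurring; insert radius 12 mm
acrylic_disk <- function(n = 256, insert_hu = 120, radius = 12) {
  body_r <- min(40, n * 350 / 1024 / 2 - 2)
  spec <- phantom_spec("disk", c(body_r, body_r), background_hu = 0,
                       inserts = list(insert_spec("acrylic", c(0, 0),
                                                  min(radius, body_r - 4),
                                                  insert_hu)),
                       outside_hu = 0)
  radius <- min(radius, body_r - 4)
  g <- grid_geometry(n, pixel_spacing = 350 / 1024)
  list(spec = spec, grid = g, img = render_phantom(spec, g), radius = radius)
}

# near-flat spectral shape (white noise) at a given SD
white_model <- function(noise_sd) {
  recon_model("white", 0, nps_shape(1, 1e6), noise_sd = noise_sd)
}

low_pass_model <- function(noise_sd) {
  recon_model("low-pass", 0, nps_shape(1, 0.12, 0, 0.35), noise_sd = noise_sd)
}

band_pass_model <- function(noise_sd) {
  recon_model("band-pass", 0, nps_shape(0.1, 0.12, 1, 0.35), noise_sd = noise_sd)
}

# generating means of the default two-arm cohort, one value per
# comparison row in compare_arms() row order
default_generating_means <- function() {
  nz <- default_noise_rows()
  cn <- default_cnr_rows()
  probs <- default_rating_probs()
  items <- names(probs$a)
  list(a = c(nz$mean_a, cn$mean_a,
             vapply(probs$a, function(p) sum(p * 1:5), numeric(1))),
       b = c(nz$mean_b, cn$mean_b,
             vapply(probs$b, function(p) sum(p * 1:5), numeric(1))),
       labels = c(nz$anatomy, cn$site, items))
}

# brute-force two-sided signed-rank p over all 2^n sign patterns
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}
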