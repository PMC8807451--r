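#' Clinical cohort specification
#'
#' Describes a paired two-arm abdominopelvic cohort for simulation: per-
#' anatomy objective-noise distributions, per-site CNR distributions, and
#' per-item 5-point rating distributions for each reconstruction arm,
#' plus the paired correlation between arms. The defaults are the study
#' conditions of a 36-patient low-dose contrast-enhanced abdominopelvic
#' comparison of an MBIR-like and a DLR-like arm: objective noise (HU)
#' liver 6.4+/-0.1 vs 9.5+/-0.1, upper fat 7.0+/-2.3 vs 8.7+/-1.9, psoas
#' 6.4+/-1.4 vs 9.0+/-1.4, bladder 6.4+/-1.4 vs 9.2+/-1.6, lower fat
#' 7.4+/-1.9 vs 9.3+/-1.7; CNR liver 5.2+/-0.0 vs 4.2+/-0.1 and pelvis
#' 6.8+/-0.2 vs 5.3+/-0.0; and 5-point ratings whose expected values match
#' the reported subjective scores (MBIR noise graded 4-5, other MBIR items
#' 1-3; all DLR items 3-5).
#'
#' Because CNR is a derived quantity, the generator draws each patient's
#' CNR from its row distribution and back-solves the liver (or pelvic
#' organ) ROI mean as `reference + CNR * fat SD`, so the downstream CNR
#' computation recovers the generating distribution through the real
#' formula rather than by construction.
#'
#' @param n_patients number of paired patients.
#' @param noise data.frame with columns `anatomy`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b` (HU) for anatomies liver, upper_fat, psoas, bladder,
#'   lower_fat.
#' @param cnr data.frame with columns `site`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b` for sites liver, pelvis.
#' @param ratings named list (`a`, `b`) of named lists item -> length-5
#'   probability vector over scores 1..5.
#' @param arms length-2 character, arm labels (a = first, b = second).
#' @param paired_correlation correlation in `[0, 1)` between arms for the
#'   continuous draws.
#' @param reviewer_agreement probability the second reviewer repeats the
#'   first reviewer's score (else an independent redraw).
#' @param seed integer seed used by [generate_cohort()].
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 36L,
                        noise = default_noise_rows(),
                        cnr = default_cnr_rows(),
                        ratings = default_rating_probs(),
                        arms = c("MBIR", "DLR"),
                        paired_correlation = 0.5,
                        reviewer_agreement = 0.8,
                        seed = 1L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop("n_patients must be at least 1")
  if (paired_correlation < 0 || paired_correlation >= 1)
    stop("paired_correlation must lie in [0, 1)")
  if (any(c(noise$sd_a, noise$sd_b, cnr$sd_a, cnr$sd_b) < 0))
    stop("generating SDs must be nonnegative")
  for (arm in c("a", "b")) {
    for (item in names(ratings[[arm]])) {
      p <- ratings[[arm]][[item]]
      if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop(sprintf("rating probabilities for '%s' (%s) must be a length-5 simplex",
                     item, arm))
    }
  }
  structure(list(n_patients = n_patients, noise = noise, cnr = cnr,
                 ratings = ratings, arms = arms,
                 paired_correlation = paired_correlation,
                 reviewer_agreement = reviewer_agreement,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default generating parameters for the two-arm cohort
#'
#' @return `default_noise_rows()` and `default_cnr_rows()` return
#'   data.frames of Gaussian row parameters (arm a then arm b);
#'   `default_rating_probs()` a nested list of 5-point probability vectors.
#' @export
default_noise_rows <- function() {
  data.frame(
    anatomy = c("liver", "upper_fat", "psoas", "bladder", "lower_fat"),
    mean_a  = c(6.4, 7.0, 6.4, 6.4, 7.4),
    sd_a    = c(0.1, 2.3, 1.4, 1.4, 1.9),
    mean_b  = c(9.5, 8.7, 9.0, 9.2, 9.3),
    sd_b    = c(0.1, 1.9, 1.4, 1.6, 1.7))
}

#' @rdname default_noise_rows
#' @export
default_cnr_rows <- function() {
  data.frame(site = c("liver", "pelvis"),
             mean_a = c(5.2, 6.8), sd_a = c(0.0, 0.2),
             mean_b = c(4.2, 5.3), sd_b = c(0.1, 0.0))
}

#' @rdname default_noise_rows
#' @export
default_rating_probs <- function() {
  list(
    a = list(   # smooth, low-frequency-heavy arm: low noise, poor texture
      noise_liver           = c(0.0, 0.0, 0.0, 0.2, 0.8),  # mean 4.8
      noise_pelvis          = c(0.0, 0.0, 0.0, 0.6, 0.4),  # mean 4.4
      diagnostic_confidence = c(0.2, 0.6, 0.2, 0.0, 0.0),  # mean 2.0
      appearance_liver      = c(0.1, 0.6, 0.3, 0.0, 0.0),  # mean 2.2
      appearance_pelvis     = c(0.2, 0.6, 0.2, 0.0, 0.0),  # mean 2.0
      texture_liver         = c(0.1, 0.6, 0.3, 0.0, 0.0),  # mean 2.2
      texture_pelvis        = c(0.2, 0.6, 0.2, 0.0, 0.0)), # mean 2.0
    b = list(   # sharper, fine-grain arm: more noise, better texture
      noise_liver           = c(0.0, 0.0, 0.3, 0.6, 0.1),  # mean 3.8
      noise_pelvis          = c(0.0, 0.0, 0.6, 0.4, 0.0),  # mean 3.4
      diagnostic_confidence = c(0.0, 0.0, 0.3, 0.6, 0.1),  # mean 3.8
      appearance_liver      = c(0.0, 0.0, 0.2, 0.6, 0.2),  # mean 4.0
      appearance_pelvis     = c(0.0, 0.0, 0.3, 0.6, 0.1),  # mean 3.8
      texture_liver         = c(0.0, 0.0, 0.2, 0.6, 0.2),  # mean 4.0
      texture_pelvis        = c(0.0, 0.0, 0.4, 0.5, 0.1))) # mean 3.7
}

# paired Gaussian draws: value_arm = mean_arm + sd_arm * z_arm with
# corr(z_a, z_b) = rho
paired_gauss <- function(n, mean_a, sd_a, mean_b, sd_b, rho) {
  z0 <- stats::rnorm(n); za <- stats::rnorm(n); zb <- stats::rnorm(n)
  ga <- sqrt(rho) * z0 + sqrt(1 - rho) * za
  gb <- sqrt(rho) * z0 + sqrt(1 - rho) * zb
  list(a = mean_a + sd_a * ga, b = mean_b + sd_b * gb)
}

draw_scores <- function(n, probs) {
  sample.int(5L, n, replace = TRUE, prob = probs)
}

#' Generate a paired synthetic cohort
#'
#' Draws `n_patients` paired patient records from a [cohort_spec()]:
#' per-anatomy ROI measurements (the liver gets 3 ROIs, all other
#' anatomies 1), two reviewers' 5-point ratings per item, and per-patient
#' dose records. Reproducible given the spec's seed.
#'
#' @param cspec a [cohort_spec()].
#' @param dose_mean,dose_sd CTDIvol generating parameters (mGy).
#' @param dlp_mean,dlp_sd dose-length-product parameters (mGy cm).
#' @return A list of class `ct_cohort` with data.frames
#'   `patients` (patient, sex, weight_kg, bmi),
#'   `measurements` (patient, arm, anatomy, roi, mean_hu, sd_hu),
#'   `ratings` (patient, arm, reviewer, item, score), and
#'   `doses` (patient, ctdi_vol, dlp), plus the generating `spec`.
#' @export
generate_cohort <- function(cspec, dose_mean = 4.2, dose_sd = 1.6,
                            dlp_mean = 243.2, dlp_sd = 106.0) {
  stopifnot(inherits(cspec, "cohort_spec"))
  n <- cspec$n_patients
  rho <- cspec$paired_correlation
  set.seed(cspec$seed)

  # objective noise (sd_hu) per anatomy, paired across arms
  nz <- lapply(seq_len(nrow(cspec$noise)), function(i) {
    r <- cspec$noise[i, ]
    paired_gauss(n, r$mean_a, r$sd_a, r$mean_b, r$sd_b, rho)
  })
  names(nz) <- cspec$noise$anatomy
  nz <- lapply(nz, function(v) lapply(v, function(x) pmax(x, 0.1)))

  # CNR draws, back-solved into ROI means through the CNR formulas
  cnr_draw <- lapply(seq_len(nrow(cspec$cnr)), function(i) {
    r <- cspec$cnr[i, ]
    paired_gauss(n, r$mean_a, r$sd_a, r$mean_b, r$sd_b, rho)
  })
  names(cnr_draw) <- cspec$cnr$site

  # per-patient baseline ROI means (HU), shared across arms
  psoas_mean   <- stats::rnorm(n, 55, 6)
  bladder_mean <- stats::rnorm(n, 10, 4)
  ufat_mean    <- stats::rnorm(n, -100, 10)
  lfat_mean    <- stats::rnorm(n, -100, 10)

  meas <- list()
  for (arm_i in 1:2) {
    arm_key <- c("a", "b")[arm_i]
    arm_lab <- cspec$arms[arm_i]
    liver_target <- psoas_mean + cnr_draw$liver[[arm_key]] * nz$upper_fat[[arm_key]]
    organ_mean   <- bladder_mean + cnr_draw$pelvis[[arm_key]] * nz$lower_fat[[arm_key]]
    # liver: 3 ROIs jittered around the patient's target mean and noise
    for (roi in 1:3) {
      meas[[length(meas) + 1L]] <- data.frame(
        patient = seq_len(n), arm = arm_lab, anatomy = "liver", roi = roi,
        mean_hu = liver_target + stats::rnorm(n, 0, 2),
        sd_hu = pmax(nz$liver[[arm_key]] + stats::rnorm(n, 0, 0.3), 0.1))
    }
    one_roi <- function(anatomy, mu, sd) data.frame(
      patient = seq_len(n), arm = arm_lab, anatomy = anatomy, roi = 1L,
      mean_hu = mu, sd_hu = sd)
    meas[[length(meas) + 1L]] <- one_roi("upper_fat", ufat_mean, nz$upper_fat[[arm_key]])
    meas[[length(meas) + 1L]] <- one_roi("psoas", psoas_mean, nz$psoas[[arm_key]])
    meas[[length(meas) + 1L]] <- one_roi("bladder", bladder_mean, nz$bladder[[arm_key]])
    meas[[length(meas) + 1L]] <- one_roi("pelvic_organ", organ_mean, nz$bladder[[arm_key]])
    meas[[length(meas) + 1L]] <- one_roi("lower_fat", lfat_mean, nz$lower_fat[[arm_key]])
  }
  measurements <- do.call(rbind, meas)

  # two reviewers' 5-point ratings per item and arm
  rat <- list()
  for (arm_i in 1:2) {
    arm_key <- c("a", "b")[arm_i]
    arm_lab <- cspec$arms[arm_i]
    for (item in names(cspec$ratings[[arm_key]])) {
      p <- cspec$ratings[[arm_key]][[item]]
      s1 <- draw_scores(n, p)
      repeat_mask <- stats::runif(n) < cspec$reviewer_agreement
      s2 <- ifelse(repeat_mask, s1, draw_scores(n, p))
      rat[[length(rat) + 1L]] <- data.frame(
        patient = rep(seq_len(n), 2L), arm = arm_lab,
        reviewer = rep(1:2, each = n), item = item, score = c(s1, s2))
    }
  }
  ratings <- do.call(rbind, rat)

  sex <- rep(c("M", "F"), length.out = n)
  patients <- data.frame(
    patient = seq_len(n), sex = sex,
    weight_kg = truncated_normal(n, 57.1, 11.7, lower = 30),
    bmi = truncated_normal(n, 22.5, 3.5, lower = 12))
  doses <- data.frame(
    patient = seq_len(n),
    ctdi_vol = truncated_normal(n, dose_mean, dose_sd, lower = 0.5),
    dlp = truncated_normal(n, dlp_mean, dlp_sd, lower = 20))

  structure(list(patients = patients, measurements = measurements,
                 ratings = ratings, doses = doses, spec = cspec),
            class = "ct_cohort")
}

# redraw-below-bound truncated normal (bias-free above `lower`)
truncated_normal <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate the reference patient group
#'
#' Body-size data for the routine-protocol reference group used in the
#' unpaired body-weight / body-mass-index comparison (defaults: n = 101,
#' weight 57.3 +/- 14.4 kg, BMI 21.9 +/- 4.5 kg/m^2).
#'
#' @param n group size.
#' @param weight_mean,weight_sd weight parameters (kg).
#' @param bmi_mean,bmi_sd BMI parameters (kg/m^2).
#' @param seed integer seed.
#' @return data.frame with columns `patient`, `weight_kg`, `bmi`.
#' @export
generate_reference_group <- function(n = 101L, weight_mean = 57.3,
                                     weight_sd = 14.4, bmi_mean = 21.9,
                                     bmi_sd = 4.5, seed = 1L) {
  set.seed(as.integer(seed))
  data.frame(patient = seq_len(n),
             weight_kg = truncated_normal(n, weight_mean, weight_sd, lower = 25),
             bmi = truncated_normal(n, bmi_mean, bmi_sd, lower = 10))
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat(sprintf("<ct_cohort> %d paired patients, arms %s vs %s; %d ROI rows, %d ratings\n",
              x$spec$n_patients, x$spec$arms[1], x$spec$arms[2],
              nrow(x$measurements), nrow(x$ratings)))
  invisible(x)
}

#' Write cohort tables as CSV
#'
#' @param cohort a `ct_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ct_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "measurements.csv",
                            "ratings.csv", "doses.csv"))
  utils::write.csv(cohort$patients, paths[1], row.names = FALSE)
  utils::write.csv(cohort$measurements, paths[2], row.names = FALSE)
  utils::write.csv(cohort$ratings, paths[3], row.names = FALSE)
  utils::write.csv(cohort$doses, paths[4], row.names = FALSE)
  invisible(paths)
}
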