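#' Contrast-to-noise ratios
#'
#' Liver CNR is (mean hepatic CT number - psoas CT number) divided by the
#' noise (SD) in the upper abdominal subcutaneous fat; pelvic CNR is
#' (prostate/uterus CT number - urinary bladder CT number) divided by the
#' noise in the lower abdominal subcutaneous fat.
#'
#' @param liver_mean,psoas_mean,organ_mean,bladder_mean ROI mean CT
#'   numbers (HU).
#' @param upper_fat_sd,lower_fat_sd reference fat-ROI noise (HU), positive.
#' @return Dimensionless CNR (sign preserved).
#' @examples
#' cnr_liver(110, 60, 10)   # 5
#' @export
cnr_liver <- function(liver_mean, psoas_mean, upper_fat_sd) {
  if (any(upper_fat_sd <= 0)) stop("fat noise must be positive")
  (liver_mean - psoas_mean) / upper_fat_sd
}

#' @rdname cnr_liver
#' @export
cnr_pelvis <- function(organ_mean, bladder_mean, lower_fat_sd) {
  if (any(lower_fat_sd <= 0)) stop("fat noise must be positive")
  (organ_mean - bladder_mean) / lower_fat_sd
}

# per-patient scalar measurements for one anatomy and arm; the liver's
# 3 ROIs are aggregated by the arithmetic mean of their values
patient_values <- function(measurements, anatomy, arm,
                           column = c("sd_hu", "mean_hu")) {
  column <- match.arg(column)
  sel <- measurements$anatomy == anatomy & measurements$arm == arm
  if (!any(sel)) stop(sprintf("no '%s' measurements for arm '%s'", anatomy, arm))
  sub <- measurements[sel, ]
  agg <- tapply(sub[[column]], sub$patient, mean)
  missing <- setdiff(unique(measurements$patient), as.numeric(names(agg)))
  if (length(missing) > 0L)
    stop(sprintf("anatomy '%s' missing for patient(s) %s", anatomy,
                 paste(missing, collapse = ", ")))
  agg[order(as.numeric(names(agg)))]
}

#' Objective noise across a cohort
#'
#' The per-patient noise for an anatomy is its ROI SD value (for the
#' liver, the arithmetic mean of the 3 hepatic ROI SDs); the cohort
#' objective noise is the mean of these values across patients, reported
#' with their SD.
#'
#' @param measurements data.frame with columns `patient`, `arm`,
#'   `anatomy`, `mean_hu`, `sd_hu` (one row per ROI).
#' @param anatomy one of liver, upper_fat, psoas, bladder, pelvic_organ,
#'   lower_fat.
#' @param arm arm label to select.
#' @return List with `mean`, `sd`, `n`, and the per-patient `values`.
#' @export
objective_noise <- function(measurements, anatomy, arm) {
  v <- patient_values(measurements, anatomy, arm, "sd_hu")
  if (length(v) < 2L) stop("objective noise needs at least 2 patients")
  list(mean = mean(v), sd = stats::sd(v), n = length(v),
       values = as.numeric(v))
}

#' Per-patient CNR values for a cohort arm
#'
#' @param measurements as in [objective_noise()].
#' @param site `"liver"` or `"pelvis"`.
#' @param arm arm label.
#' @return Numeric vector of per-patient CNR values (patient order).
#' @export
cohort_cnr <- function(measurements, site = c("liver", "pelvis"), arm) {
  site <- match.arg(site)
  if (site == "liver") {
    cnr_liver(patient_values(measurements, "liver", arm, "mean_hu"),
              patient_values(measurements, "psoas", arm, "mean_hu"),
              patient_values(measurements, "upper_fat", arm, "sd_hu"))
  } else {
    cnr_pelvis(patient_values(measurements, "pelvic_organ", arm, "mean_hu"),
               patient_values(measurements, "bladder", arm, "mean_hu"),
               patient_values(measurements, "lower_fat", arm, "sd_hu"))
  }
}

#' Effective dose from the dose-length product
#'
#' Effective dose (mSv) is the DLP (mGy cm) multiplied by the anatomical
#' conversion coefficient, 0.015 mSv mGy^-1 cm^-1 for the abdomen and
#' pelvis. Full precision is kept internally; use `round(x, 1)` at the
#' presentation layer.
#'
#' @param dlp dose-length product in mGy cm, nonnegative.
#' @param k conversion coefficient in mSv mGy^-1 cm^-1.
#' @return Effective dose in mSv.
#' @examples
#' effective_dose(243.2)        # 3.648 -> presented as 3.6 mSv
#' @export
effective_dose <- function(dlp, k = 0.015) {
  if (any(dlp < 0)) stop("dlp must be nonnegative")
  if (any(k < 0)) stop("k must be nonnegative")
  dlp * k
}

#' Contrast-material volume and flow rate
#'
#' Converts a weight-based iodine dose into injected volume and rate:
#' `volume = weight * dose_per_kg / concentration`, delivered over
#' `duration` seconds.
#'
#' @param body_weight patient weight in kg.
#' @param dose_per_kg iodine load in mgI per kg of body weight.
#' @param concentration contrast-material concentration in mgI/mL.
#' @param duration injection duration in s.
#' @return List with `volume_ml` and `rate_ml_s`.
#' @examples
#' cm_dose(60, 312, 300, 45)    # 62.4 mL at ~1.39 mL/s
#' @export
cm_dose <- function(body_weight, dose_per_kg, concentration, duration) {
  if (any(c(body_weight, dose_per_kg, concentration, duration) <= 0))
    stop("all contrast-material inputs must be positive")
  volume <- body_weight * dose_per_kg / concentration
  list(volume_ml = volume, rate_ml_s = volume / duration)
}

#' Percent reduction relative to a reference
#'
#' @param new_value reduced quantity.
#' @param reference_value reference quantity, positive.
#' @return `(1 - new_value / reference_value) * 100`.
#' @examples
#' percent_reduction(312, 520)  # 40
#' @export
percent_reduction <- function(new_value, reference_value) {
  if (any(reference_value <= 0)) stop("reference_value must be positive")
  (1 - new_value / reference_value) * 100
}
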