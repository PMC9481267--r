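#' Configuration for the synthetic cohort generator
#'
#' Bundles every tunable of the synthetic pressure-plate cohort. The
#' anthropometric defaults reproduce the study population the pipeline was
#' designed for (first-year students, healthy 175.69 +/- 8.23 cm and
#' 68.65 +/- 9.00 kg, injured 177.70 +/- 8.04 cm and 69.75 +/- 8.63 kg,
#' injured fraction 35/155), sampled at 250 Hz with five trials per foot and
#' condition.
#'
#' @param n_subjects Number of subjects to simulate (>= 2).
#' @param injured_fraction Probability that a subject develops a
#'   lower-extremity overuse injury within the follow-up window.
#' @param effect_size Relative increase `delta` of the injured subjects'
#'   forefoot loading. With `effect_measurement = "peak_pressure"` (default)
#'   it multiplies the forefoot peak-to-mean factor by `1 + delta`, so the
#'   injury signal is concentrated in forefoot peak pressures; with
#'   `"amplitude"` it multiplies the forefoot mean-pressure bump itself, and
#'   so propagates into mean pressure, mean force and vertical force.
#' @param effect_gait Gaits the injury effect acts on. Default `"run"`:
#'   walking trials then stay label-free, which keeps the walking-based
#'   scale normalisation neutral.
#' @param timing_shift Stance-fraction shift of the injured subjects'
#'   forefoot activation window (default 0).
#' @param stance_duration_run,stance_duration_walk Mean and SD of stance
#'   duration in seconds, `c(mean, sd)`.
#' @param sampling_rate Pressure-plate sampling rate in Hz.
#' @param n_trials_per_condition Footfalls recorded per foot and condition.
#' @param walk_vf_peak,run_vf_peak Target peak vertical force as a multiple
#'   of body weight while walking / running.
#' @param shod_attenuation Multiplicative amplitude attenuation of shod
#'   relative to barefoot trials (shoes cushion the plate signal, leaving
#'   footwear conditions partially redundant).
#' @param subject_amp_sd,subject_peak_sd SD of the per-subject log-normal
#'   zone-amplitude and peak-factor multipliers (between-subject
#'   variability).
#' @param trial_amp_sd,peak_noise_sd SD of the per-trial log-normal zone
#'   amplitude noise and the per-sample peak-pressure noise.
#' @param templates Zone activation templates, see
#'   [default_zone_templates()].
#' @param walk_full_measurements If `TRUE`, walking footfalls carry the full
#'   zone-resolved measurement set; by default they carry only the
#'   whole-foot vertical force, which is all the downstream pipeline uses.
#' @param seed Integer seed making the cohort reproducible.
#' @param effect_measurement See `effect_size`.
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 10, seed = 1)
#' cfg$injured_fraction
cohort_config <- function(n_subjects = 155,
                          injured_fraction = 35 / 155,
                          effect_size = 0.3,
                          effect_measurement = c("peak_pressure", "amplitude"),
                          effect_gait = c("run", "all"),
                          timing_shift = 0,
                          stance_duration_run = c(0.22, 0.02),
                          stance_duration_walk = c(0.70, 0.05),
                          sampling_rate = 250,
                          n_trials_per_condition = 5,
                          walk_vf_peak = 1.1,
                          run_vf_peak = 2.5,
                          shod_attenuation = 0.9,
                          subject_amp_sd = 0.15,
                          subject_peak_sd = 0.10,
                          trial_amp_sd = 0.08,
                          peak_noise_sd = 0.05,
                          templates = default_zone_templates(),
                          walk_full_measurements = FALSE,
                          seed = 1L) {
  effect_measurement <- match.arg(effect_measurement)
  effect_gait <- match.arg(effect_gait)
  if (n_subjects < 2) abort("n_subjects must be >= 2")
  if (injured_fraction < 0 || injured_fraction > 1) {
    abort("injured_fraction must be in [0, 1]")
  }
  if (injured_fraction == 0 || injured_fraction == 1) {
    abort("injured_fraction of 0 or 1 yields a single-class cohort; both outcome classes are required")
  }
  if (effect_size < 0) abort("effect_size must be >= 0")
  if (sampling_rate <= 0) abort("sampling_rate must be positive")
  if (n_trials_per_condition < 1) abort("n_trials_per_condition must be >= 1")
  check_zone_templates(templates)

  structure(
    list(
      n_subjects = as.integer(n_subjects),
      injured_fraction = injured_fraction,
      effect_size = effect_size,
      effect_measurement = effect_measurement,
      effect_gait = effect_gait,
      timing_shift = timing_shift,
      stance_duration_run = stance_duration_run,
      stance_duration_walk = stance_duration_walk,
      sampling_rate = sampling_rate,
      n_trials_per_condition = as.integer(n_trials_per_condition),
      walk_vf_peak = walk_vf_peak,
      run_vf_peak = run_vf_peak,
      shod_attenuation = shod_attenuation,
      subject_amp_sd = subject_amp_sd,
      subject_peak_sd = subject_peak_sd,
      trial_amp_sd = trial_amp_sd,
      peak_noise_sd = peak_noise_sd,
      templates = templates,
      walk_full_measurements = walk_full_measurements,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  subjects:", x$n_subjects,
      sprintf("(injured fraction %.3f)", x$injured_fraction), "\n")
  cat("  effect: delta =", x$effect_size, "on", x$effect_measurement,
      "| gait:", x$effect_gait, "\n")
  cat("  sampling:", x$sampling_rate, "Hz,",
      x$n_trials_per_condition, "trials/foot/condition\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

# Anthropometric reference values of the study population by outcome class.
cohort_anthropometrics <- function() {
  tibble::tibble(
    injured    = c(FALSE, TRUE),
    height_mean = c(175.69, 177.70),
    height_sd   = c(8.23, 8.04),
    weight_mean = c(68.65, 69.75),
    weight_sd   = c(9.00, 8.63),
    p_male      = c(83 / 120, 26 / 35)
  )
}
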