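#' Sample one synthetic subject profile
#'
#' Draws anthropometrics from class-specific normal distributions matching
#' the study population (see [cohort_config()]), assigns the injury label
#' Bernoulli(`injured_fraction`), and attaches the subject's latent loading
#' style: log-normal per-zone amplitude and peak-factor multipliers that
#' make subjects differ from each other consistently across their trials.
#' Uses the current RNG stream.
#'
#' @param config A [cohort_config()].
#' @param subject_id Identifier for the new subject.
#' @return A one-row tibble with columns `subject_id`, `sex`, `height`
#'   (cm), `weight` (kg), `bmi`, `shoe_size` (EU), `injured`, plus the
#'   latent list-columns `zone_amp` and `peak_mult`.
#' @export
#' @examples
#' set.seed(1)
#' sample_subject_profile(cohort_config(n_subjects = 10))
sample_subject_profile <- function(config, subject_id = "S001") {
  injured <- rbinom(1, 1, config$injured_fraction) == 1
  ref <- cohort_anthropometrics()
  ref <- ref[ref$injured == injured, ]
  height <- max(rnorm(1, ref$height_mean, ref$height_sd), 100)
  weight <- max(rnorm(1, ref$weight_mean, ref$weight_sd), 30)
  sex <- if (rbinom(1, 1, ref$p_male) == 1) "male" else "female"
  shoe_size <- round(2 * (0.23 * height + 1.5 + rnorm(1, 0, 0.8))) / 2
  nz <- length(foot_zones())
  tibble::tibble(
    subject_id = subject_id,
    sex = sex,
    height = height,
    weight = weight,
    bmi = weight / (height / 100)^2,
    shoe_size = shoe_size,
    injured = injured,
    zone_amp = list(stats::setNames(exp(rnorm(nz, 0, config$subject_amp_sd)),
                                    foot_zones())),
    peak_mult = list(stats::setNames(exp(rnorm(nz, 0, config$subject_peak_sd)),
                                     foot_zones()))
  )
}

# squared-sine activation bump on [onset, offset] of stance (u in [0,1])
zone_bump <- function(u, onset, offset) {
  inside <- u >= onset & u <= offset
  out <- numeric(length(u))
  out[inside] <- sin(pi * (u[inside] - onset) / (offset - onset))^2
  out
}

# Deterministic per-(subject, gait) pressure scale: calibrated so the
# noise-free healthy template's vertical-force peak equals the configured
# multiple of body weight (in newtons).
gait_scale <- function(profile, gait, config) {
  tpl <- config$templates
  mult <- profile$zone_amp[[1]][tpl$zone]
  u <- seq(0, 1, length.out = 256)
  vf <- numeric(length(u))
  for (i in seq_len(nrow(tpl))) {
    vf <- vf + tpl$amplitude[i] * mult[i] * tpl$area[i] *
      zone_bump(u, tpl$onset_frac[i], tpl$offset_frac[i])
  }
  target <- if (gait == "run") config$run_vf_peak else config$walk_vf_peak
  target * 9.81 * profile$weight / max(vf)
}

#' Simulate all measurements of one footfall
#'
#' Generates a single synthetic stance phase: per-zone mean-pressure bumps
#' (squared sine on each zone's activation window, heel zones early, toes
#' late), peak pressure as mean pressure times a noisy peak factor bounded
#' below by 1, mean force as mean pressure times zone area (exactly), and
#' whole-foot vertical force as the sum of zone mean forces (exactly).
#' Injured subjects receive the configured forefoot effect (see
#' [cohort_config()]). Uses the current RNG stream.
#'
#' @param profile One-row profile tibble from [sample_subject_profile()].
#' @param footwear `"barefoot"` or `"shod"`.
#' @param gait `"walk"` or `"run"`.
#' @param foot `"left"` or `"right"`.
#' @param trial_index Trial number within the condition.
#' @param config A [cohort_config()].
#' @return A tibble with one row per series (10 zones x 3 measurements plus
#'   whole-foot vertical force): metadata columns, series length `n`, and a
#'   `values` list-column.
#' @export
#' @examples
#' set.seed(1)
#' p <- sample_subject_profile(cohort_config(n_subjects = 10))
#' trial <- simulate_trial(p, "barefoot", "run", "left", config = cohort_config(10))
#' trial
simulate_trial <- function(profile, footwear, gait, foot, trial_index = 1L,
                           config = cohort_config()) {
  tpl <- config$templates
  check_zone_templates(tpl)
  dur_par <- if (gait == "run") config$stance_duration_run else config$stance_duration_walk
  dur <- max(rnorm(1, dur_par[1], dur_par[2]), 0.4 * dur_par[1])
  n_samp <- max(as.integer(round(dur * config$sampling_rate)), 10L)
  u <- seq(0, 1, length.out = n_samp)

  effect_on <- profile$injured &&
    (config$effect_gait == "all" || gait == config$effect_gait)
  is_fore <- tpl$zone %in% forefoot_zones()

  onset <- tpl$onset_frac
  offset <- tpl$offset_frac
  if (effect_on && config$timing_shift != 0) {
    onset[is_fore] <- pmin(pmax(onset[is_fore] + config$timing_shift, 0), 0.99)
    offset[is_fore] <- pmin(pmax(offset[is_fore] + config$timing_shift, 0.01), 1)
  }

  amp <- tpl$amplitude * profile$zone_amp[[1]][tpl$zone] *
    gait_scale(profile, gait, config)
  if (footwear == "shod") amp <- amp * config$shod_attenuation
  if (effect_on && config$effect_measurement == "amplitude") {
    amp[is_fore] <- amp[is_fore] * (1 + config$effect_size)
  }
  amp <- amp * exp(rnorm(nrow(tpl), 0, config$trial_amp_sd))

  pf <- tpl$peak_factor * profile$peak_mult[[1]][tpl$zone]
  if (effect_on && config$effect_measurement == "peak_pressure") {
    pf[is_fore] <- pf[is_fore] * (1 + config$effect_size)
  }

  nz <- nrow(tpl)
  mp <- matrix(0, n_samp, nz)
  pk <- matrix(0, n_samp, nz)
  for (i in seq_len(nz)) {
    mp[, i] <- amp[i] * zone_bump(u, onset[i], offset[i])
    pk[, i] <- mp[, i] * pmax(1, pf[i] * exp(rnorm(n_samp, 0, config$peak_noise_sd)))
  }
  mf <- sweep(mp, 2, tpl$area, `*`)
  # plain left-to-right sum so vf equals Reduce(`+`) of the zone forces exactly
  vf <- mf[, 1]
  for (j in 2:nz) vf <- vf + mf[, j]

  k <- 3L * nz + 1L
  tibble::new_tibble(list(
    subject_id = rep(profile$subject_id, k),
    footwear = rep(footwear, k),
    gait = rep(gait, k),
    foot = rep(foot, k),
    trial_index = rep(as.integer(trial_index), k),
    measurement = c(rep("peak_pressure", nz), rep("mean_pressure", nz),
                    rep("mean_force", nz), "vertical_force"),
    zone = c(tpl$zone, tpl$zone, tpl$zone, "whole_foot"),
    n = rep(n_samp, k),
    values = c(lapply(seq_len(nz), function(j) pk[, j]),
               lapply(seq_len(nz), function(j) mp[, j]),
               lapply(seq_len(nz), function(j) mf[, j]),
               list(vf))
  ), nrow = k)
}

#' Generate a full synthetic pressure-plate cohort
#'
#' Reproducibly simulates the study's acquisition protocol: for every
#' subject, `n_trials_per_condition` running footfalls per foot both
#' barefoot and shod, plus the same number of barefoot walking footfalls per
#' foot (walking carries only the whole-foot vertical force unless
#' `walk_full_measurements` is set, as the pipeline uses walking solely for
#' scale normalisation). Trial lengths vary stochastically around the
#' configured stance durations.
#'
#' @param config A [cohort_config()]; `config$seed` fixes the whole cohort.
#' @return An object of class `pressure_cohort`: a list with `trials` (one
#'   row per series, `values` list-column), `profiles`, `roster`
#'   (`subject_id`, `outcome_class`) and the `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 4, seed = 7))
#' cohort
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  profiles <- dplyr::bind_rows(lapply(seq_len(config$n_subjects), function(i) {
    sample_subject_profile(config, sprintf("S%03d", i))
  }))
  if (length(unique(profiles$injured)) < 2) {
    abort(paste0(
      "degenerate cohort: all ", config$n_subjects, " sampled subjects fall in ",
      "one outcome class; increase n_subjects or adjust injured_fraction"))
  }

  feet <- c("left", "right")
  pieces <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    prof <- profiles[i, ]
    sub_pieces <- list()
    for (fw in c("barefoot", "shod")) {
      for (ft in feet) {
        for (tr in seq_len(config$n_trials_per_condition)) {
          sub_pieces[[length(sub_pieces) + 1L]] <-
            simulate_trial(prof, fw, "run", ft, tr, config)
        }
      }
    }
    for (ft in feet) {
      for (tr in seq_len(config$n_trials_per_condition)) {
        walk <- simulate_trial(prof, "barefoot", "walk", ft, tr, config)
        if (!config$walk_full_measurements) {
          walk <- walk[walk$measurement == "vertical_force", ]
        }
        sub_pieces[[length(sub_pieces) + 1L]] <- walk
      }
    }
    pieces[[i]] <- dplyr::bind_rows(sub_pieces)
  }

  roster <- tibble::tibble(
    subject_id = profiles$subject_id,
    outcome_class = ifelse(profiles$injured, "lower_extremity_overuse", "healthy")
  )
  structure(
    list(trials = dplyr::bind_rows(pieces), profiles = profiles,
         roster = roster, config = config),
    class = "pressure_cohort"
  )
}

#' @export
print.pressure_cohort <- function(x, ...) {
  cat("<pressure_cohort>\n")
  cat("  subjects:", nrow(x$profiles),
      sprintf("(%d injured)", sum(x$profiles$injured)), "\n")
  cat("  series:", nrow(x$trials),
      sprintf("(%d footfalls)",
              nrow(dplyr::distinct(x$trials, .data$subject_id, .data$footwear,
                                   .data$gait, .data$foot, .data$trial_index))),
      "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Write / read a cohort as plain-text artifacts
#'
#' The trial store is persisted as a long-format CSV (`trials.csv`, columns
#' `subject_id, footwear, gait, foot, trial_index, measurement, zone,
#' sample_index, value`) alongside `profiles.csv`, `roster.csv`, the
#' generator configuration as `config.yaml` and a `meta.json` sidecar
#' (seed, sampling rate, generator version). Outputs are deterministic:
#' the same cohort always produces byte-identical files.
#'
#' @param cohort A `pressure_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `pressure_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pressure_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  long <- tidyr::unnest_longer(
    dplyr::mutate(cohort$trials,
                  sample_index = lapply(.data$n, seq_len)),
    c("values", "sample_index")
  )
  long <- dplyr::select(long, "subject_id", "footwear", "gait", "foot",
                        "trial_index", "measurement", "zone",
                        "sample_index", value = "values")
  readr::write_csv(long, file.path(dir, "trials.csv"))

  prof <- dplyr::mutate(
    cohort$profiles,
    zone_amp = vapply(.data$zone_amp, function(v) paste(format(v, digits = 17), collapse = ";"), ""),
    peak_mult = vapply(.data$peak_mult, function(v) paste(format(v, digits = 17), collapse = ";"), "")
  )
  readr::write_csv(prof, file.path(dir, "profiles.csv"))
  readr::write_csv(cohort$roster, file.path(dir, "roster.csv"))

  cfg <- cohort$config
  cfg$templates <- as.data.frame(cfg$templates)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         sampling_rate = cohort$config$sampling_rate,
         generator = "plantarisk",
         generator_version = as.character(utils::packageVersion("plantarisk"))),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  long <- readr::read_csv(file.path(dir, "trials.csv"), show_col_types = FALSE)
  trials <- long |>
    dplyr::arrange(.data$subject_id, .data$footwear, .data$gait, .data$foot,
                   .data$trial_index, .data$measurement, .data$zone,
                   .data$sample_index) |>
    dplyr::group_by(.data$subject_id, .data$footwear, .data$gait, .data$foot,
                    .data$trial_index, .data$measurement, .data$zone) |>
    dplyr::summarise(n = dplyr::n(), values = list(.data$value),
                     .groups = "drop")

  prof <- readr::read_csv(file.path(dir, "profiles.csv"), show_col_types = FALSE)
  parse_named <- function(s) {
    v <- as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    stats::setNames(v, foot_zones())
  }
  prof$zone_amp <- lapply(prof$zone_amp, parse_named)
  prof$peak_mult <- lapply(prof$peak_mult, parse_named)

  roster <- readr::read_csv(file.path(dir, "roster.csv"), show_col_types = FALSE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg$templates <- tibble::as_tibble(as.data.frame(cfg$templates))
  config <- do.call(cohort_config, cfg)
  structure(list(trials = trials, profiles = prof, roster = roster,
                 config = config),
            class = "pressure_cohort")
}
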