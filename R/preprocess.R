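#' Per-subject scale factors from barefoot walking
#'
#' Each subject's scale factor is the maximum of their barefoot-walking
#' whole-foot vertical force, the normaliser that removes between-subject
#' differences in body weight and speed.
#'
#' @param trials A trial tibble (see [simulate_cohort()]).
#' @return A tibble `subject_id`, `scale_factor`.
#' @export
walking_scale_factors <- function(trials) {
  walk <- dplyr::filter(trials, .data$gait == "walk",
                        .data$footwear == "barefoot",
                        .data$measurement == "vertical_force")
  if (nrow(walk) == 0) abort("no barefoot-walking vertical-force trials")
  sf <- walk |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(scale_factor = max(unlist(.data$values)),
                     .groups = "drop")
  if (any(sf$scale_factor <= 0)) {
    abort("all-zero walking vertical force for at least one subject")
  }
  sf
}

#' Scale-normalise a subject signal table
#'
#' Divides every peak-pressure, mean-pressure and mean-force signal by the
#' subject's maximum barefoot-walking vertical force. Relative ratios
#' between zones are untouched; vertical-force signals keep their raw
#' scale.
#'
#' @param signals A signal tibble (`subject_id`, `footwear`, `measurement`,
#'   `zone`, `values` list-column).
#' @param walk_trials Trial tibble containing the barefoot-walking
#'   vertical-force series, or a precomputed tibble from
#'   [walking_scale_factors()].
#' @return The signal tibble with scaled `values` and a `scale_factor`
#'   column.
#' @export
normalize_scale <- function(signals, walk_trials) {
  sf <- if (all(c("subject_id", "scale_factor") %in% names(walk_trials)) &&
            !"values" %in% names(walk_trials)) {
    walk_trials
  } else {
    walking_scale_factors(walk_trials)
  }
  missing <- setdiff(unique(signals$subject_id), sf$subject_id)
  if (length(missing) > 0) {
    abort(paste0("missing walking data for: ", paste(missing, collapse = ", ")))
  }
  out <- dplyr::left_join(signals, sf, by = "subject_id")
  scale_it <- out$measurement != "vertical_force"
  out$values[scale_it] <- purrr::map2(out$values[scale_it],
                                      out$scale_factor[scale_it],
                                      function(v, s) v / s)
  out
}

#' Align, average and scale-normalise a cohort's trials
#'
#' The full preprocessing stage: (1) pick, per footwear, the longest
#' running trial over all subjects as the shared reference; (2) zero-pad
#' every running series to the reference length at the padding that
#' maximises 2D-histogram mutual information with the reference's series of
#' the same zone and measurement; (3) average each subject's aligned trials
#' pointwise into one signal per (zone, measurement, footwear), pooling
#' both feet unless `pool_feet = FALSE`; (4) divide pressure and force
#' signals by the subject's maximum barefoot-walking vertical force.
#' Walking trials are only used for step (4).
#'
#' @param trials A trial tibble (see [simulate_cohort()]), or a
#'   `pressure_cohort`.
#' @param n_bins Histogram bins per dimension for the MI objective.
#' @param pool_feet Average left and right feet together (default) or keep
#'   them separate.
#' @return An object of class `signal_set`: a list with `signals` (tibble
#'   with `values` list-column and `scale_factor`), `references`,
#'   `alignment` (per-series left/right pad and MI), `scale_factors` and
#'   `options`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 3, seed = 2))
#' sig <- preprocess_trials(cohort)
#' sig
preprocess_trials <- function(trials, n_bins = 256, pool_feet = TRUE) {
  if (inherits(trials, "pressure_cohort")) trials <- trials$trials
  run <- dplyr::filter(trials, .data$gait == "run")
  if (nrow(run) == 0) abort("no running trials to preprocess")
  footwears <- intersect(c("barefoot", "shod"), unique(run$footwear))
  references <- lapply(footwears, function(fw) select_reference(trials, fw))
  names(references) <- footwears

  aligned <- vector("list", length(footwears))
  meta <- vector("list", length(footwears))
  for (f in seq_along(footwears)) {
    fw <- footwears[f]
    sub <- dplyr::filter(run, .data$footwear == fw)
    ref <- references[[fw]]
    key <- paste(sub$measurement, sub$zone, sep = "|")
    unknown <- setdiff(unique(key), names(ref$signals))
    if (length(unknown) > 0) {
      abort(paste0("series absent from reference footfall: ",
                   paste(unknown, collapse = ", ")))
    }
    padded <- vector("list", nrow(sub))
    lp <- rp <- integer(nrow(sub))
    mi <- numeric(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      a <- align_trial(sub$values[[i]], ref$signals[[key[i]]], n_bins)
      padded[[i]] <- a$padded
      lp[i] <- a$left_pad
      rp[i] <- a$right_pad
      mi[i] <- a$mi
    }
    sub$values <- padded
    sub$n <- ref$length
    aligned[[f]] <- sub
    meta[[f]] <- dplyr::mutate(
      dplyr::select(sub, "subject_id", "footwear", "foot", "trial_index",
                    "measurement", "zone"),
      left_pad = lp, right_pad = rp, mi = mi)
  }
  aligned <- dplyr::bind_rows(aligned)

  group_cols <- c("subject_id", "footwear", "measurement", "zone")
  if (!pool_feet) group_cols <- c(group_cols, "foot")
  signals <- aligned |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(n = .data$n[1],
                     values = list(aggregate_trials(.data$values)),
                     .groups = "drop")

  scale_factors <- walking_scale_factors(trials)
  signals <- normalize_scale(signals, scale_factors)

  structure(
    list(signals = signals,
         references = lapply(references, function(r) r[c("footwear", "length",
                                                         "subject_id", "foot",
                                                         "trial_index")]),
         alignment = dplyr::bind_rows(meta),
         scale_factors = scale_factors,
         options = list(n_bins = n_bins, pool_feet = pool_feet)),
    class = "signal_set"
  )
}

#' @export
print.signal_set <- function(x, ...) {
  cat("<signal_set>\n")
  cat("  subjects:", length(unique(x$signals$subject_id)), "\n")
  cat("  signals/subject:",
      nrow(x$signals) / length(unique(x$signals$subject_id)), "\n")
  lens <- vapply(x$references, function(r) r$length, integer(1))
  cat("  reference lengths:",
      paste(sprintf("%s=%d", names(lens), lens), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn preprocess_trials Long-format tibble of the aligned,
#'   normalised signals (one row per sample).
#' @param x A `signal_set`.
#' @param ... Unused.
#' @export
tidy.signal_set <- function(x, ...) {
  tidyr::unnest_longer(
    dplyr::mutate(x$signals, sample_index = lapply(.data$n, seq_len)),
    c("values", "sample_index")
  ) |>
    dplyr::select("subject_id", "footwear", "measurement", "zone",
                  "sample_index", value = "values")
}
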