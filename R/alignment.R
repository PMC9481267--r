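#' 2D-histogram mutual information between two equally long signals
#'
#' Estimates the mutual information (in nats) between paired samples
#' `(x[t], y[t])` from their joint histogram on an `n_bins` x `n_bins`
#' grid. Each axis spans that signal's own `[min, max]`; empty joint cells
#' contribute nothing. This is the objective the zero-padding alignment
#' maximises.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @param n_bins Number of histogram bins per dimension (default 256).
#' @return A non-negative scalar, the MI estimate in nats.
#' @export
#' @examples
#' x <- rep(c(0, 1, 2, 3), each = 8)
#' mutual_information(x, x)  # log(4)
mutual_information <- function(x, y, n_bins = 256) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("signals must have length >= 2")
  stopifnot(n_bins >= 2)
  mi_hist2d_cpp(as.numeric(x), as.numeric(y), as.integer(n_bins))
}

#' Select the padding reference for a footwear condition
#'
#' The reference is the longest running trial over all subjects for the
#' given footwear; every run trial of that footwear is zero-padded to the
#' reference length and aligned against the reference footfall's series of
#' the same zone and measurement. Length ties are broken by the lowest
#' `(subject_id, trial_index, foot)`.
#'
#' @param trials A trial tibble as produced by [simulate_cohort()] (one row
#'   per series, `values` list-column).
#' @param footwear `"barefoot"` or `"shod"`.
#' @return A list with `footwear`, `length`, `subject_id`, `foot`,
#'   `trial_index`, and `signals`: a named list (`measurement|zone`) of the
#'   reference footfall's series.
#' @export
select_reference <- function(trials, footwear) {
  run <- dplyr::filter(trials, .data$gait == "run",
                       .data$footwear == !!footwear)
  if (nrow(run) == 0) abort(paste0("no run trials for footwear ", footwear))
  best <- run |>
    dplyr::distinct(.data$subject_id, .data$foot, .data$trial_index, .data$n) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$subject_id, .data$trial_index,
                   .data$foot) |>
    dplyr::slice(1)
  ref_rows <- dplyr::filter(run, .data$subject_id == best$subject_id,
                            .data$foot == best$foot,
                            .data$trial_index == best$trial_index)
  list(
    footwear = footwear,
    length = best$n,
    subject_id = best$subject_id,
    foot = best$foot,
    trial_index = best$trial_index,
    signals = stats::setNames(ref_rows$values,
                              paste(ref_rows$measurement, ref_rows$zone,
                                    sep = "|"))
  )
}

#' Optimally align one trial to a reference by zero padding
#'
#' Tries every split of `length(reference) - length(values)` zeros between
#' the beginning and the end of the trial and keeps the padding that
#' maximises the 2D-histogram mutual information between the padded signal
#' and the reference. Time-related structure inside the trial is untouched
#' (no stretching or resampling). MI ties are broken by the smallest left
#' pad.
#'
#' @param values Numeric trial signal.
#' @param reference Numeric reference signal, at least as long.
#' @param n_bins Histogram bins per dimension for the MI objective.
#' @return A list with `left_pad`, `right_pad`, `padded` (length of the
#'   reference) and `mi` (the achieved mutual information).
#' @export
#' @examples
#' ref <- c(0, 0, 1, 4, 9, 4, 1, 0, 0)
#' align_trial(c(1, 4, 9, 4, 1), ref)$left_pad
align_trial <- function(values, reference, n_bins = 256) {
  n <- length(values)
  L <- length(reference)
  if (n > L) abort("trial longer than reference")
  if (n == L) {
    return(list(left_pad = 0L, right_pad = 0L, padded = as.numeric(values),
                mi = mutual_information(values, reference, n_bins)))
  }
  profile <- pad_mi_profile_cpp(as.numeric(values), as.numeric(reference),
                                as.integer(n_bins))
  left <- which.max(profile) - 1L   # first maximum = smallest left pad
  list(
    left_pad = left,
    right_pad = L - n - left,
    padded = c(rep(0, left), as.numeric(values), rep(0, L - n - left)),
    mi = profile[left + 1L]
  )
}

#' Pointwise average of aligned trials
#'
#' Aggregates a subject's aligned run trials of one (zone, measurement,
#' footwear) combination into a single signal by the pointwise arithmetic
#' mean.
#'
#' @param aligned A list of equal-length numeric vectors.
#' @return A numeric vector of the shared length.
#' @export
aggregate_trials <- function(aligned) {
  if (length(aligned) == 0) abort("no trials to aggregate")
  lens <- lengths(aligned)
  if (length(unique(lens)) != 1) abort("aligned trials must share one length")
  Reduce(`+`, aligned) / length(aligned)
}
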