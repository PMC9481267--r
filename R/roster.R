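#' Apply the study's inclusion and exclusion criteria to an outcome roster
#'
#' Subjects whose follow-up outcome is either `healthy` or
#' `lower_extremity_overuse` are included (label 0 / 1 respectively);
#' subjects with an acute injury, an unknown injury status, or
#' missing/invalid values are excluded. A subject with any acute record is
#' out of the overuse taxonomy and always excluded.
#'
#' @param roster A data frame with columns `subject_id` and
#'   `outcome_class`; one row per subject. Valid classes: `healthy`,
#'   `lower_extremity_overuse`, `acute`, `unknown`, `missing_invalid`.
#' @return A tibble of the included subjects (`subject_id`,
#'   `outcome_class`, `label`), with the per-class counts attached as the
#'   `"counts"` attribute (also available via [roster_counts()]).
#' @export
#' @examples
#' roster <- tibble::tibble(
#'   subject_id = c("a", "b", "c"),
#'   outcome_class = c("healthy", "lower_extremity_overuse", "acute")
#' )
#' apply_inclusion_criteria(roster)
apply_inclusion_criteria <- function(roster) {
  stopifnot(is.data.frame(roster),
            all(c("subject_id", "outcome_class") %in% names(roster)))
  valid <- c("healthy", "lower_extremity_overuse", "acute", "unknown",
             "missing_invalid")
  bad <- setdiff(unique(roster$outcome_class), valid)
  if (length(bad) > 0) {
    abort(paste0("invalid outcome_class value(s): ", paste(bad, collapse = ", ")))
  }
  dup <- roster$subject_id[duplicated(roster$subject_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate subject_id in roster: ",
                 paste(unique(dup), collapse = ", ")))
  }
  included <- roster |>
    dplyr::filter(.data$outcome_class %in%
                    c("healthy", "lower_extremity_overuse")) |>
    dplyr::mutate(label = as.integer(.data$outcome_class ==
                                       "lower_extremity_overuse")) |>
    tibble::as_tibble()
  attr(included, "counts") <- roster_counts(roster)
  included
}

#' @rdname apply_inclusion_criteria
#' @return `roster_counts()` returns a tibble with one row per outcome
#'   class (`outcome_class`, `n`, `included`).
#' @export
roster_counts <- function(roster) {
  roster |>
    dplyr::count(.data$outcome_class, name = "n") |>
    dplyr::mutate(included = .data$outcome_class %in%
                    c("healthy", "lower_extremity_overuse")) |>
    tibble::as_tibble()
}

#' Feature budget under the 10% rule
#'
#' Logistic regression overfits when the number of features exceeds roughly
#' 10% of the sample size; the group-exclusion analysis therefore trains on
#' `floor(n / 10)` features (15 for the study's 155 subjects).
#'
#' @param n_subjects Number of subjects.
#' @return An integer feature budget.
#' @export
#' @examples
#' feature_budget(155)
feature_budget <- function(n_subjects) {
  stopifnot(n_subjects >= 10)
  as.integer(floor(n_subjects / 10))
}
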