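#' Assign every feature to its foot-area, measurement and footwear groups
#'
#' Each signal-derived feature belongs to exactly one group of each kind:
#' its anatomical foot area (10 zones; whole-foot vertical-force features
#' carry no foot area), its measurement type (peak pressure, mean pressure,
#' mean force, vertical force, or general person characteristics), and its
#' footwear condition (barefoot/shod; person characteristics carry none).
#' Groups of different kinds overlap; groups within a kind are disjoint.
#'
#' @param feature_names Character vector of feature-table column names.
#' @return A tibble `kind`, `group`, `feature` (long format, one row per
#'   feature-group membership).
#' @export
#' @examples
#' assign_feature_groups(c(
#'   "metatarsal_1__mean_force__shod__maximum",
#'   "person__characteristic__na__sex"
#' ))
assign_feature_groups <- function(feature_names) {
  parsed <- parse_feature_names(feature_names)
  known_zone <- parsed$zone %in% c(foot_zones(), "whole_foot", "person")
  if (any(!known_zone)) {
    abort(paste0("unknown zone in feature name(s): ",
                 paste(head(parsed$feature[!known_zone], 3), collapse = ", ")))
  }
  area <- parsed |>
    dplyr::filter(.data$zone %in% foot_zones()) |>
    dplyr::transmute(kind = "foot_area", group = .data$zone, .data$feature)
  meas <- parsed |>
    dplyr::transmute(
      kind = "measurement",
      group = ifelse(.data$zone == "person",
                     "general_person_characteristics", .data$measurement),
      .data$feature)
  fw <- parsed |>
    dplyr::filter(.data$footwear %in% c("barefoot", "shod")) |>
    dplyr::transmute(kind = "footwear", group = .data$footwear, .data$feature)
  dplyr::bind_rows(area, meas, fw)
}

#' Group-exclusion importance analysis
#'
#' Quantifies how much each group of features (foot area, measurement
#' type, footwear condition) contributes to the predictions. A baseline
#' leave-one-out run selects the `budget` top-ranked features per fold
#' from the full table (the 10%-rule budget, `floor(N/10)`, by default);
#' for each group, the same run is repeated with that group's features
#' removed before ranking. Both deltas are oriented so that *positive*
#' means the excluded model performed better: `delta_auc` is excluded
#' minus baseline AUC, `delta_brier` is baseline minus excluded Brier
#' (Brier is a loss). A negative delta therefore marks a group the model
#' needs. Rank 1 within each kind is the most important group (most
#' negative `delta_auc`, ties broken by the most negative `delta_brier`).
#' A group whose features are never selected in either run leaves the
#' predictions unchanged and gets deltas of exactly 0.
#'
#' @param feature_table A [build_feature_table()] tibble.
#' @param budget Features selected per fold (default `floor(N/10)`).
#' @param C,max_iter Passed to the model fits.
#' @return A tibble of class `group_impact`: `kind`, `rank`, `group`,
#'   `delta_auc`, `delta_brier`, `auc`, `brier`, with the baseline
#'   `loocv_result` attached as attribute `"baseline"`.
#' @export
group_exclusion_analysis <- function(feature_table, budget = NULL, C = 1,
                                     max_iter = 100) {
  n <- nrow(feature_table)
  if (is.null(budget)) budget <- feature_budget(n)
  feat_cols <- setdiff(names(feature_table), c("subject_id", "injured"))
  groups <- assign_feature_groups(feat_cols)

  baseline <- run_loocv(feature_table, grid = budget, C = C,
                        max_iter = max_iter)

  combos <- dplyr::distinct(groups, .data$kind, .data$group)
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    members <- groups$feature[groups$kind == combos$kind[i] &
                                groups$group == combos$group[i]]
    keep <- setdiff(feat_cols, members)
    if (length(keep) < budget) {
      abort(paste0("excluding group '", combos$group[i],
                   "' leaves fewer features than the budget"))
    }
    excl <- run_loocv(
      feature_table[, c("subject_id", "injured", keep)],
      grid = budget, C = C, max_iter = max_iter)
    res[[i]] <- tibble::tibble(
      kind = combos$kind[i], group = combos$group[i],
      auc = excl$auc, brier = excl$brier,
      delta_auc = excl$auc - baseline$auc,
      delta_brier = baseline$brier - excl$brier)
  }
  out <- dplyr::bind_rows(res) |>
    dplyr::group_by(.data$kind) |>
    dplyr::arrange(.data$delta_auc, .data$delta_brier, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("kind", "rank", "group", "delta_auc", "delta_brier",
                  "auc", "brier")
  attr(out, "baseline") <- baseline
  class(out) <- c("group_impact", class(out))
  out
}

#' @describeIn group_exclusion_analysis Bar chart of delta-AUC per group,
#'   faceted by kind; more negative bars mark more important groups.
#' @param object A `group_impact` tibble.
#' @param ... Unused.
#' @export
autoplot.group_impact <- function(object, ...) {
  df <- dplyr::mutate(object,
                      group = stats::reorder(.data$group, -.data$delta_auc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_auc, y = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$kind), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = expression(Delta ~ "AUC when group excluded"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Fold-occurrence of selected features
#'
#' A feature "occurs" in a fold when it survives both selection stages:
#' chosen by the univariate filter *and* kept with a nonzero weight by the
#' L1 penalty. Features occurring in at least `threshold` of the folds are
#' reported (boundary inclusive), sorted by foot area and descending
#' occurrence.
#'
#' @param loocv A `loocv_result` from [run_loocv()].
#' @param threshold Minimum fold fraction (default 0.10).
#' @return A tibble `zone`, `measurement`, `footwear`, `feature_id`,
#'   `occurrence` (percent of folds).
#' @export
feature_occurrence <- function(loocv, threshold = 0.10) {
  stopifnot(inherits(loocv, "loocv_result"))
  n_folds <- nrow(loocv$folds)
  survived <- purrr::map2(loocv$folds$selected, loocv$folds$nonzero, intersect)
  counts <- table(unlist(survived))
  occ <- tibble::tibble(feature = names(counts),
                        occurrence = 100 * as.numeric(counts) / n_folds)
  occ <- dplyr::filter(occ, .data$occurrence >= 100 * threshold)
  parsed <- parse_feature_names(occ$feature)
  dplyr::bind_cols(parsed[, c("zone", "measurement", "footwear",
                              "feature_id")],
                   occ["occurrence"]) |>
    dplyr::arrange(factor(.data$zone, c(foot_zones(), "whole_foot", "person")),
                   dplyr::desc(.data$occurrence))
}
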