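#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive receives a higher score
#' than a randomly chosen negative, with ties counted one half — the
#' normalized Mann-Whitney U statistic, computed from ranks.
#'
#' @param labels Binary labels (0/1), both classes present.
#' @param probabilities Numeric scores, same length.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc_score(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.8))  # 0.75
auc_score <- function(labels, probabilities) {
  y <- as.integer(labels)
  p <- as.numeric(probabilities)
  if (length(y) != length(p)) abort("labels and probabilities differ in length")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(p)   # average ranks handle ties as 1/2
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary
#' outcomes, \eqn{BS = N^{-1} \sum_i (p_i - y_i)^2}: 0 for perfectly
#' calibrated (and correct) probabilities, at most 1.
#'
#' @param labels Binary labels (0/1).
#' @param probabilities Predicted probabilities in \[0, 1\].
#' @return Brier score in \[0, 1\].
#' @export
#' @examples
#' brier_score(c(0, 1), c(0.8, 0.8))  # 0.34
brier_score <- function(labels, probabilities) {
  y <- as.numeric(labels)
  p <- as.numeric(probabilities)
  if (length(y) != length(p)) abort("labels and probabilities differ in length")
  if (any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  if (!all(y %in% c(0, 1))) abort("labels must be 0/1")
  mean((p - y)^2)
}

#' Leave-one-subject-out cross-validation of the full selection + model
#' pipeline
#'
#' For every subject, the remaining N-1 rows are used to (1) rank features
#' by ANOVA F, (2) choose the number of features `k` from `grid` by
#' training AUC, and (3) fit the L1-penalised logistic model; the held-out
#' subject then receives one out-of-fold probability. Feature ranking,
#' standardization and fitting never see the held-out row, which is what
#' keeps the estimate leakage-free. Pooled AUC and Brier score are
#' computed over the N out-of-fold probabilities. Undefined feature values
#' (`NA`) are imputed with training-fold medians.
#'
#' @param feature_table A [build_feature_table()] tibble (or any data
#'   frame with `subject_id`, `injured` and numeric feature columns).
#' @param grid Candidate numbers of features per fold.
#' @param C Inverse L1 penalty strength.
#' @param max_iter Solver iteration cap.
#' @param leaky If `TRUE`, deliberately performs feature selection once on
#'   the full data before splitting — the textbook leakage mistake,
#'   provided only to demonstrate how much it inflates the AUC. Never use
#'   for reporting.
#' @return An object of class `loocv_result`: `predictions` (tibble
#'   `subject_id`, `label`, `probability`), `folds` (per-fold `k_best`,
#'   selected and nonzero feature lists), `auc`, `brier`, `n`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 12, seed = 3,
#'                                         injured_fraction = 0.4))
#' sig <- preprocess_trials(cohort)
#' ft <- build_feature_table(sig, cohort$profiles, feature_bank(fft_k_max = 5))
#' res <- run_loocv(ft, grid = c(5, 10))
#' glance(res)
run_loocv <- function(feature_table, grid = c(5, 10, 15, 20, 25), C = 1,
                      max_iter = 100, leaky = FALSE) {
  stopifnot(is.data.frame(feature_table),
            all(c("subject_id", "injured") %in% names(feature_table)))
  ids <- feature_table$subject_id
  y <- as.integer(feature_table$injured)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    abort("each outcome class needs at least 2 subjects for LOOCV")
  }
  x <- as.matrix(feature_table[, setdiff(names(feature_table),
                                         c("subject_id", "injured"))])
  n <- nrow(x)

  na_cols <- which(colSums(is.na(x)) > 0)

  leak_selected <- NULL
  if (leaky) {
    full_sel <- select_k(impute_na(x, x, na_cols), y, grid = grid, C = C,
                         max_iter = max_iter)
    leak_selected <- full_sel$selected
  }

  prob <- numeric(n)
  k_best <- integer(n)
  selected <- vector("list", n)
  nonzero <- vector("list", n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    xte <- x[i, , drop = FALSE]
    xtr_i <- impute_na(xtr, xtr, na_cols)
    xte_i <- impute_na(xte, xtr, na_cols)
    if (!is.null(leak_selected)) {
      fit <- train_l1_logistic(xtr_i[, leak_selected, drop = FALSE], y[-i],
                               C = C, max_iter = max_iter)
      sel <- list(k_best = length(leak_selected), selected = leak_selected,
                  model = fit)
    } else {
      sel <- select_k(xtr_i, y[-i], grid = grid, C = C, max_iter = max_iter)
    }
    prob[i] <- predict_probability(sel$model,
                                   xte_i[, sel$selected, drop = FALSE])
    k_best[i] <- sel$k_best
    selected[[i]] <- sel$selected
    nonzero[[i]] <- names(sel$model$weights)[sel$model$weights != 0]
  }

  structure(
    list(
      predictions = tibble::tibble(subject_id = ids, label = y,
                                   probability = prob),
      folds = tibble::tibble(subject_id = ids, k_best = k_best,
                             n_selected = lengths(selected),
                             n_nonzero = lengths(nonzero),
                             selected = selected, nonzero = nonzero),
      auc = auc_score(y, prob),
      brier = brier_score(y, prob),
      n = n, grid = grid, C = C, leaky = leaky
    ),
    class = "loocv_result"
  )
}

# median imputation of NA columns using training rows only
impute_na <- function(x, train, na_cols) {
  if (length(na_cols) == 0) return(x)
  for (j in na_cols) {
    med <- median(train[, j], na.rm = TRUE)
    if (!is.finite(med)) med <- 0
    x[is.na(x[, j]), j] <- med
  }
  x
}

#' @export
print.loocv_result <- function(x, ...) {
  cat("<loocv_result>", x$n, "subjects",
      if (x$leaky) "(LEAKY selection, demonstration only)" else "", "\n")
  cat(sprintf("  AUC = %.3f | Brier = %.3f\n", x$auc, x$brier))
  cat(sprintf("  k per fold: mean %.1f, median %s\n",
              mean(x$folds$k_best), median(x$folds$k_best)))
  cat(sprintf("  nonzero weights per fold: mean %.1f\n",
              mean(x$folds$n_nonzero)))
  invisible(x)
}

#' @describeIn run_loocv Out-of-fold predictions as a tibble.
#' @param x A `loocv_result`.
#' @param ... Unused.
#' @export
tidy.loocv_result <- function(x, ...) x$predictions

#' @describeIn run_loocv One-row summary (`auc`, `brier`, `n`,
#'   `n_injured`, `mean_k`, `median_k`, `mean_nonzero`).
#' @export
glance.loocv_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, brier = x$brier, n = x$n,
    n_injured = sum(x$predictions$label),
    mean_k = mean(x$folds$k_best),
    median_k = median(x$folds$k_best),
    mean_nonzero = mean(x$folds$n_nonzero)
  )
}

#' @describeIn run_loocv ROC curve of the pooled out-of-fold probabilities.
#' @param object A `loocv_result`.
#' @export
autoplot.loocv_result <- function(object, ...) {
  y <- object$predictions$label
  p <- object$predictions$probability
  ord <- order(-p)
  tpr <- c(0, cumsum(y[ord] == 1) / sum(y == 1))
  fpr <- c(0, cumsum(y[ord] == 0) / sum(y == 0))
  df <- tibble::tibble(fpr = fpr, tpr = tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Leave-one-subject-out ROC (AUC = %.3f, Brier = %.3f)",
                      object$auc, object$brier)
    ) +
    ggplot2::theme_minimal()
}
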