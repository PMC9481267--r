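#' Rank features by one-way ANOVA F-statistic
#'
#' Scores every feature with the two-class one-way ANOVA F-statistic
#' (between-class over within-class variance) and returns a rank-ordered
#' tibble, the filter step of the per-fold feature selection. Constant
#' features score 0 and rank last; a perfectly separating feature receives
#' the largest finite score.
#'
#' @param x A numeric matrix or data frame of features (rows = subjects).
#' @param y Binary labels (0/1), both classes present.
#' @return A tibble `feature`, `statistic`, `rank`, ordered by descending
#'   score (ties keep column order).
#' @export
#' @examples
#' x <- cbind(signal = c(0, 0, 1, 1), noise = c(1, 0, 1, 0))
#' rank_features(x, c(0, 0, 1, 1))
rank_features <- function(x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) abort("both classes must be present")
  n <- nrow(x)
  i1 <- y == 1
  n1 <- sum(i1)
  n0 <- n - n1
  m1 <- colMeans(x[i1, , drop = FALSE])
  m0 <- colMeans(x[!i1, , drop = FALSE])
  m <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((x[i1, , drop = FALSE] - rep(m1, each = n1))^2) +
    colSums((x[!i1, , drop = FALSE] - rep(m0, each = n0))^2)
  f <- ssb * (n - 2) / ssw
  f[ssw == 0 & ssb > 0] <- .Machine$double.xmax   # perfect separation
  f[ssb == 0] <- 0                                # constant / identical means
  f[!is.finite(f)] <- 0
  ord <- order(-f)
  tibble::tibble(feature = colnames(x)[ord], statistic = unname(f[ord]),
                 rank = seq_along(f))
}

#' Choose the number of features by training-set AUC
#'
#' For each `k` in the grid, fits the L1-penalised logistic regression on
#' the `k` top-ranked features and scores the AUC on the same training
#' rows; returns the `k` with the highest training AUC (ties broken by the
#' smallest `k`). If fewer features than `min(grid)` are available, `k` is
#' clamped to the number of features.
#'
#' @param x Training feature matrix or data frame.
#' @param y Training labels (0/1).
#' @param grid Candidate numbers of features.
#' @param C Inverse L1 penalty strength passed to
#'   [train_l1_logistic()].
#' @param max_iter Solver iteration cap.
#' @param ranked Optional precomputed [rank_features()] result.
#' @return A list (class `selection_result`): `k_best`, `selected`
#'   (ordered feature names), `scores` (tibble `k`, `train_auc`), `model`
#'   (the winning [train_l1_logistic()] fit) and `ranked`.
#' @export
select_k <- function(x, y, grid = c(5, 10, 15, 20, 25), C = 1,
                     max_iter = 100, ranked = NULL) {
  if (length(grid) == 0) abort("grid must be nonempty")
  x <- as.matrix(x)
  if (is.null(ranked)) ranked <- rank_features(x, y)
  p <- ncol(x)
  grid_used <- sort(unique(pmin(as.integer(grid), p)))
  if (any(grid > p)) {
    inform(paste0("fewer features (", p, ") than requested k; grid clamped"))
  }
  fits <- vector("list", length(grid_used))
  aucs <- numeric(length(grid_used))
  for (i in seq_along(grid_used)) {
    k <- grid_used[i]
    feats <- ranked$feature[seq_len(k)]
    fits[[i]] <- train_l1_logistic(x[, feats, drop = FALSE], y, C = C,
                                   max_iter = max_iter)
    aucs[i] <- auc_score(y, predict_probability(fits[[i]],
                                                x[, feats, drop = FALSE]))
  }
  best <- which.max(aucs)   # first max = smallest k on ties
  structure(
    list(k_best = grid_used[best],
         selected = ranked$feature[seq_len(grid_used[best])],
         scores = tibble::tibble(k = grid_used, train_auc = aucs),
         model = fits[[best]],
         ranked = ranked),
    class = "selection_result"
  )
}

#' L1-penalised logistic regression on standardized features
#'
#' Features are z-scored with training means and SDs, then a lasso-penalised
#' logistic model is fitted at the fixed penalty `lambda = 1 / (n * C)`
#' (so `C` is the familiar inverse regularisation strength, default 1).
#' The L1 penalty drives coefficients of uninformative features to exactly
#' zero, acting as a second feature-selection stage.
#'
#' @param x Feature matrix or data frame (training rows only).
#' @param y Binary labels (0/1), both classes present.
#' @param C Inverse penalty strength; smaller values penalise harder.
#' @param max_iter Iteration cap for the coordinate-descent solver; a
#'   warning is raised if it is reached without convergence.
#' @return An object of class `l1_logit`: `weights` (named, on the
#'   standardized scale), `intercept`, `center`, `scale`, `lambda`, `C`.
#' @export
#' @examples
#' set.seed(1)
#' x <- cbind(a = rnorm(40), b = rnorm(40))
#' y <- as.integer(x[, "a"] + rnorm(40, 0, 0.5) > 0)
#' fit <- train_l1_logistic(x, y)
#' tidy(fit)
train_l1_logistic <- function(x, y, C = 1, max_iter = 100) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) < 2) abort("need at least 2 training rows")
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, `/`)

  n <- nrow(xs)
  lambda <- 1 / (n * C)
  # decreasing path ending exactly at the target lambda stabilises the
  # coordinate-descent warm starts
  lambda_max <- max(abs(crossprod(xs, y - mean(y))) / n, lambda * 1.001)
  path <- exp(seq(log(lambda_max * 1.05), log(lambda), length.out = 25))
  path[length(path)] <- lambda

  # glmnet requires >= 2 columns; pad a void column for univariate fits
  padded <- ncol(xs) == 1
  if (padded) xs <- cbind(xs, `.void.` = 0)

  # max_iter caps the coordinate-descent passes per penalty value
  converged <- TRUE
  fit <- withCallingHandlers(
    glmnet::glmnet(xs, y, family = "binomial", alpha = 1,
                   lambda = path, standardize = FALSE,
                   maxit = max_iter * length(path)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("Convergence", msg)) converged <<- FALSE
      if (grepl("dangerous ground|Convergence", msg)) {
        invokeRestart("muffleWarning")   # small-fold noise; summarised below
      }
    })
  if (!converged || min(fit$lambda) > lambda * 1.000001) {
    warn(paste0("L1 solver stopped at the iteration cap (max_iter = ",
                max_iter, ") before full convergence"))
  }
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = lambda, exact = FALSE))
  intercept <- cf[1]
  w <- cf[-1]
  names(w) <- colnames(xs)
  if (padded) {
    w <- w[setdiff(names(w), ".void.")]
    center <- center[names(w)]
    scl <- scl[names(w)]
  }
  structure(
    list(weights = w, intercept = intercept, center = center, scale = scl,
         lambda = lambda, C = C, max_iter = max_iter, converged = converged),
    class = "l1_logit"
  )
}

#' Predicted injury probability
#'
#' Applies the stored standardization and returns the logistic sigmoid of
#' the linear predictor.
#'
#' @param model An `l1_logit` fit.
#' @param newdata A matrix, data frame or named numeric vector containing
#'   every selected feature.
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(model, newdata) {
  stopifnot(inherits(model, "l1_logit"))
  feats <- names(model$weights)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, names(newdata)))
  }
  newdata <- as.matrix(newdata)
  missing <- setdiff(feats, colnames(newdata))
  if (length(missing) > 0) {
    abort(paste0("missing feature(s): ", paste(head(missing, 3), collapse = ", ")))
  }
  z <- sweep(sweep(newdata[, feats, drop = FALSE], 2, model$center),
             2, model$scale, `/`)
  as.numeric(plogis(z %*% model$weights + model$intercept))
}

#' @export
print.l1_logit <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat("<l1_logit>", length(x$weights), "features,", nz, "nonzero |",
      sprintf("lambda = %.4g (C = %g)\n", x$lambda, x$C))
  invisible(x)
}

#' @describeIn train_l1_logistic Coefficients as a tibble (`term`,
#'   `estimate` on the standardized scale).
#' @param x An `l1_logit` fit.
#' @param ... Unused.
#' @export
tidy.l1_logit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", names(x$weights)),
                 estimate = c(x$intercept, unname(x$weights)))
}

#' @describeIn train_l1_logistic One-row model summary.
#' @export
glance.l1_logit <- function(x, ...) {
  tibble::tibble(n_features = length(x$weights),
                 n_nonzero = sum(x$weights != 0),
                 lambda = x$lambda, C = x$C)
}
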