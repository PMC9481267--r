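#' Discrete Fourier coefficient of a series
#'
#' Returns \eqn{A_k = \sum_{m=0}^{n-1} X_m \exp(-2\pi i m k / n)}, the
#' k-th DFT coefficient. `fft_angle()` returns its phase in radians, with
#' the convention that a numerically zero coefficient (modulus below
#' `1e-12`) has angle 0.
#'
#' @param x Numeric series.
#' @param k Coefficient index, `0 <= k < length(x)`.
#' @param z A complex number.
#' @return `fft_coefficient()`: a complex scalar. `fft_angle()`: a real
#'   angle in `(-pi, pi]`.
#' @export
#' @examples
#' n <- 32
#' x <- cos(2 * pi * 3 * (0:(n - 1)) / n)
#' fft_coefficient(x, 3)   # 16 + 0i
fft_coefficient <- function(x, k) {
  n <- length(x)
  if (k < 0 || k >= n) abort("k must satisfy 0 <= k < length(x)")
  fft(as.numeric(x))[k + 1]
}

#' @rdname fft_coefficient
#' @export
fft_angle <- function(z) {
  ifelse(Mod(z) < 1e-12, 0, Arg(z))
}

#' Autoregressive coefficients by conditional least squares
#'
#' Fits \eqn{X_t = \phi_0 + \sum_{i=1}^{k} \phi_i X_{t-i} + \epsilon_t} by
#' ordinary least squares of \eqn{X_t} on an intercept and the `k` lagged
#' values (conditional on the first `k` observations). Coefficient `i` is
#' the lag-`i` weight; `phi_0` is the intercept.
#'
#' @param x Numeric series, length `> max_lag + 1`, not constant.
#' @param max_lag Maximum lag `k` (default 10).
#' @return A named numeric vector `phi_0 ... phi_k`.
#' @export
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.6), 2000))
#' round(ar_coefficients(x, 2)["phi_1"], 1)
ar_coefficients <- function(x, max_lag = 10) {
  n <- length(x)
  if (n <= max_lag + 1) abort("series too short for the requested max_lag")
  if (sd(x) == 0) abort("degenerate input: constant series has no AR fit")
  emb <- stats::embed(as.numeric(x), max_lag + 1)
  y <- emb[, 1]
  X <- cbind(1, emb[, -1, drop = FALSE])
  dec <- qr(X)
  if (dec$rank < ncol(X)) abort("degenerate input: singular AR design matrix")
  phi <- qr.coef(dec, y)
  stats::setNames(as.numeric(phi), paste0("phi_", 0:max_lag))
}

#' Configure the time-series feature bank
#'
#' Defines which summary features [extract_features()] computes from one
#' signal: basic moments, absolute energy, linear-trend slope/intercept,
#' autocorrelations, FFT coefficient angles and magnitudes, AR
#' coefficients, and the count of local maxima. The bank approximates, at a
#' configurable and much smaller scale, the exhaustive default feature set
#' of automated time-series featurisation tools.
#'
#' @param acf_lags Autocorrelation lags to include.
#' @param fft_k_max Highest FFT coefficient index (capped at `n - 1` per
#'   signal).
#' @param ar_max_lag Maximum lag of the AR fit.
#' @param include Character vector of base feature ids to include.
#' @param extra Named list of additional feature functions
#'   (`function(x) -> scalar`), appended under their names.
#' @return A list of class `feature_bank`.
#' @export
#' @examples
#' feature_bank(fft_k_max = 10)
feature_bank <- function(acf_lags = 1:10,
                         fft_k_max = 99,
                         ar_max_lag = 10,
                         include = c("maximum", "minimum", "mean",
                                     "standard_deviation", "abs_energy",
                                     "linear_trend_slope",
                                     "linear_trend_intercept", "skewness",
                                     "kurtosis", "count_local_maxima"),
                         extra = list()) {
  stopifnot(fft_k_max >= 0, ar_max_lag >= 1)
  structure(list(acf_lags = as.integer(acf_lags),
                 fft_k_max = as.integer(fft_k_max),
                 ar_max_lag = as.integer(ar_max_lag),
                 include = include, extra = extra),
            class = "feature_bank")
}

# feature ids produced for a signal of length n (deterministic order)
bank_feature_ids <- function(bank, n) {
  kmax <- min(bank$fft_k_max, n - 1)
  c(bank$include,
    paste0("autocorrelation_", bank$acf_lags),
    paste0("fft_angle_", 0:kmax),
    paste0("fft_magnitude_", 0:kmax),
    paste0("ar_coeff_", 0:bank$ar_max_lag, "_maxlag_", bank$ar_max_lag),
    names(bank$extra))
}

#' Extract the feature bank from one signal
#'
#' @param x Numeric signal of length >= 2.
#' @param bank A [feature_bank()].
#' @return A named numeric vector; features that are undefined for the
#'   signal (e.g. AR coefficients of a constant series) are `NA` and are
#'   imputed downstream with training-fold medians.
#' @export
#' @examples
#' extract_features(c(1, 2, 3), feature_bank(fft_k_max = 2, ar_max_lag = 1))
extract_features <- function(x, bank = feature_bank()) {
  n <- length(x)
  if (n < 2) abort("signal too short to featurise")
  x <- as.numeric(x)
  out <- list()
  s <- sd(x)
  m <- mean(x)

  base <- c(
    maximum = max(x), minimum = min(x), mean = m, standard_deviation = s,
    abs_energy = sum(x^2),
    linear_trend_slope = NA_real_, linear_trend_intercept = NA_real_,
    skewness = NA_real_, kurtosis = NA_real_,
    count_local_maxima = if (n < 3) 0 else
      sum(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n])
  )
  t <- 0:(n - 1)
  slope <- sum((t - mean(t)) * (x - m)) / sum((t - mean(t))^2)
  base["linear_trend_slope"] <- slope
  base["linear_trend_intercept"] <- m - slope * mean(t)
  if (s > 0) {
    m2 <- mean((x - m)^2)
    base["skewness"] <- mean((x - m)^3) / m2^1.5
    base["kurtosis"] <- mean((x - m)^4) / m2^2 - 3   # excess kurtosis
  }
  out$base <- base[bank$include]

  lag_max <- max(bank$acf_lags)
  ac <- if (s > 0 && n > lag_max) {
    as.numeric(acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf)[-1]
  } else {
    rep(NA_real_, lag_max)
  }
  out$acf <- stats::setNames(ac[bank$acf_lags],
                             paste0("autocorrelation_", bank$acf_lags))

  kmax <- min(bank$fft_k_max, n - 1)
  fc <- fft(x)[1:(kmax + 1)]
  out$fft <- stats::setNames(c(fft_angle(fc), Mod(fc)),
                             c(paste0("fft_angle_", 0:kmax),
                               paste0("fft_magnitude_", 0:kmax)))

  phi <- tryCatch(ar_coefficients(x, bank$ar_max_lag),
                  error = function(e) rep(NA_real_, bank$ar_max_lag + 1))
  out$ar <- stats::setNames(as.numeric(phi),
                            paste0("ar_coeff_", 0:bank$ar_max_lag,
                                   "_maxlag_", bank$ar_max_lag))

  if (length(bank$extra) > 0) {
    out$extra <- vapply(bank$extra, function(f) as.numeric(f(x)[1]),
                        numeric(1))
  }
  unlist(out, use.names = TRUE) |>
    (\(v) stats::setNames(v, sub("^(base|acf|fft|ar|extra)\\.", "", names(v))))()
}

#' Feature name grammar
#'
#' A feature column is named `zone__measurement__footwear__feature_id`,
#' e.g. `metatarsal_1__peak_pressure__shod__fft_angle_21`. Person
#' characteristics use `person__characteristic__na__<field>`. The encoding
#' is bijective: `parse_feature_names()` inverts `render_feature_name()`.
#'
#' @param zone,measurement,footwear,feature_id Name components; none may
#'   contain a double underscore.
#' @param names Character vector of rendered feature names.
#' @return `render_feature_name()`: a character vector.
#'   `parse_feature_names()`: a tibble with columns `feature`, `zone`,
#'   `measurement`, `footwear`, `feature_id`.
#' @export
#' @examples
#' nm <- render_feature_name("toes_2_5", "mean_pressure", "shod", "fft_angle_21")
#' parse_feature_names(nm)
render_feature_name <- function(zone, measurement, footwear, feature_id) {
  for (part in list(zone, measurement, footwear, feature_id)) {
    if (any(grepl("__", part, fixed = TRUE))) {
      abort("feature name components must not contain '__'")
    }
  }
  paste(zone, measurement, footwear, feature_id, sep = "__")
}

#' @rdname render_feature_name
#' @export
parse_feature_names <- function(names) {
  parts <- strsplit(names, "__", fixed = TRUE)
  bad <- lengths(parts) != 4
  if (any(bad)) {
    abort(paste0("unparseable feature name(s): ",
                 paste(head(names[bad], 3), collapse = ", ")))
  }
  m <- do.call(rbind, parts)
  tibble::tibble(feature = names, zone = m[, 1], measurement = m[, 2],
                 footwear = m[, 3], feature_id = m[, 4])
}

person_feature_names <- function() {
  render_feature_name("person", "characteristic", "na",
                      c("sex", "height", "weight", "bmi", "shoe_size"))
}

#' Build the subjects-by-features table
#'
#' Runs the feature bank over every preprocessed signal (10 zones x
#' \{peak pressure, mean pressure, mean force\} x 2 footwear conditions,
#' plus the whole-foot vertical force per footwear) and appends the person
#' characteristics (sex coded male = 1, height, weight, BMI, shoe size) and
#' the binary injury label. Column order is deterministic.
#'
#' @param signal_set A `signal_set` from [preprocess_trials()].
#' @param profiles Profile tibble with `subject_id`, `sex`, `height`,
#'   `weight`, `bmi`, `shoe_size`, `injured`.
#' @param bank A [feature_bank()].
#' @return A tibble (class `feature_table`): `subject_id`, `injured`
#'   (0/1), then one numeric column per feature.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_subjects = 3, seed = 2))
#' sig <- preprocess_trials(cohort)
#' ft <- build_feature_table(sig, cohort$profiles, feature_bank(fft_k_max = 5))
#' dim(ft)
build_feature_table <- function(signal_set, profiles, bank = feature_bank()) {
  stopifnot(inherits(signal_set, "signal_set"))
  signals <- signal_set$signals
  meas_order <- c("peak_pressure", "mean_pressure", "mean_force",
                  "vertical_force")
  zone_order <- c(foot_zones(), "whole_foot")
  signals <- signals |>
    dplyr::arrange(factor(.data$footwear, c("barefoot", "shod")),
                   factor(.data$measurement, meas_order),
                   factor(.data$zone, zone_order),
                   .data$subject_id)

  inventory <- signals |>
    dplyr::count(.data$subject_id, name = "n_signals")
  if (length(unique(inventory$n_signals)) != 1) {
    abort("signal inventory differs across subjects")
  }
  key <- signals |>
    dplyr::distinct(.data$footwear, .data$measurement, .data$zone)
  per_subject <- signals |>
    dplyr::count(.data$footwear, .data$measurement, .data$zone)
  if (any(per_subject$n != nrow(inventory))) {
    abort("signal inventory differs across subjects: a (zone, measurement, footwear) series is missing for some subject")
  }

  subjects <- sort(unique(signals$subject_id))
  rows <- vector("list", length(subjects))
  feat_names <- NULL
  for (si in seq_along(subjects)) {
    sub <- signals[signals$subject_id == subjects[si], ]
    vals <- vector("list", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      f <- extract_features(sub$values[[i]], bank)
      names(f) <- render_feature_name(sub$zone[i], sub$measurement[i],
                                      sub$footwear[i], names(f))
      vals[[i]] <- f
    }
    row <- unlist(vals, use.names = TRUE)
    if (is.null(feat_names)) {
      feat_names <- names(row)
    } else if (!identical(names(row), feat_names)) {
      abort("signal inventory differs across subjects")
    }
    rows[[si]] <- row
  }
  mat <- do.call(rbind, rows)

  prof <- profiles[match(subjects, profiles$subject_id), ]
  if (any(is.na(prof$subject_id))) abort("profiles missing for some subjects")
  person <- cbind(as.integer(prof$sex == "male"), prof$height, prof$weight,
                  prof$bmi, prof$shoe_size)
  colnames(person) <- person_feature_names()

  out <- tibble::as_tibble(cbind(as.data.frame(mat), as.data.frame(person)))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = subjects,
                   injured = as.integer(prof$injured)),
    out
  )
  attr(out, "bank") <- bank
  class(out) <- c("feature_table", class(out))
  out
}

#' @describeIn build_feature_table Expected feature-column count for given
#'   reference lengths: the bank size per signal depends on the signal
#'   length through the FFT index cap.
#' @param lengths Named integer vector of reference lengths per footwear.
#' @export
expected_feature_count <- function(bank, lengths) {
  per_fw <- vapply(lengths, function(L) length(bank_feature_ids(bank, L)),
                   integer(1))
  # 31 signals per footwear (10 zones x 3 measurements + vertical force)
  sum(31L * per_fw) + length(person_feature_names())
}
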