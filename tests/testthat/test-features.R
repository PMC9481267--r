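test_that("fft_coefficient matches the closed forms", {
  n <- 32
  m <- 0:(n - 1)
  a3 <- fft_coefficient(cos(2 * pi * 3 * m / n), 3)
  expect_equal(a3, complex(real = 16, imaginary = 0), tolerance = 1e-12)
  expect_equal(fft_angle(a3), 0)

  const <- rep(2.5, n)
  expect_equal(fft_coefficient(const, 0), complex(real = n * 2.5), tolerance = 1e-12)
  expect_equal(Mod(fft_coefficient(const, 5)), 0, tolerance = 1e-10)
  expect_equal(fft_angle(fft_coefficient(const, 5)), 0)   # zero-coef convention

  expect_equal(fft_angle(fft_coefficient(sin(2 * pi * 3 * m / n), 3)),
               -pi / 2, tolerance = 1e-12)
  expect_error(fft_coefficient(1:4, 4), "0 <= k")
  expect_error(fft_coefficient(1:4, -1), "0 <= k")
})

test_that("fft_coefficient agrees with direct O(n^2) summation", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(4:64, 1)
    x <- rnorm(n)
    for (k in 0:(n - 1)) {
      a <- fft_coefficient(x, k)
      o <- oracle_dft(x, k)
      expect_lt(Mod(a - o) / max(Mod(o), 1e-30), 1e-9)
    }
  }
})

test_that("ar_coefficients recover simulated AR parameters", {
  set.seed(3)
  x <- as.numeric(stats::arima.sim(list(ar = 0.6), 5000))
  phi <- ar_coefficients(x, 10)
  expect_equal(unname(phi["phi_1"]), 0.6, tolerance = 0.05 / 0.6)
  expect_true(all(abs(phi[paste0("phi_", 2:10)]) < 0.05))

  # AR(3) parameter recovery
  true <- c(0.5, -0.3, 0.2)
  y <- as.numeric(stats::arima.sim(list(ar = true), 5000))
  phi3 <- ar_coefficients(y, 3)
  expect_equal(unname(phi3[c("phi_1", "phi_2", "phi_3")]), true,
               tolerance = 0.05 / min(abs(true)))

  # white noise: all lag weights near zero
  w <- rnorm(5000)
  phiw <- ar_coefficients(w, 10)
  expect_true(all(abs(phiw[-1]) < 0.05))

  expect_error(ar_coefficients(rep(1, 100), 10), "constant")
  expect_error(ar_coefficients(rnorm(10), 10), "too short")
})

test_that("the feature bank computes its hand-checkable members", {
  bank <- feature_bank(acf_lags = 1:2, fft_k_max = 2, ar_max_lag = 1)
  f <- extract_features(c(1, 2, 3), bank)
  expect_equal(unname(f["abs_energy"]), 14)
  expect_equal(unname(f["maximum"]), 3)
  expect_equal(unname(f["minimum"]), 1)

  g <- extract_features(c(0, 1, 2, 3), bank)
  expect_equal(unname(g["linear_trend_slope"]), 1)
  expect_equal(unname(g["linear_trend_intercept"]), 0)

  z <- extract_features(rep(0, 10), bank)
  expect_equal(unname(z["maximum"]), 0)
  expect_true(is.na(z[paste0("ar_coeff_1_maxlag_1")]))   # degenerate AR -> NA

  expect_equal(names(f), bank_names <- {
    ids <- c(bank$include, "autocorrelation_1", "autocorrelation_2",
             "fft_angle_0", "fft_angle_1", "fft_angle_2",
             "fft_magnitude_0", "fft_magnitude_1", "fft_magnitude_2",
             "ar_coeff_0_maxlag_1", "ar_coeff_1_maxlag_1")
    ids
  })
  expect_error(extract_features(1, bank), "too short")
})

test_that("feature names round-trip through the grammar", {
  nm <- render_feature_name("toes_2_5", "mean_pressure", "shod",
                            "ar_coeff_7_maxlag_10")
  parsed <- parse_feature_names(nm)
  expect_equal(parsed$zone, "toes_2_5")
  expect_equal(parsed$measurement, "mean_pressure")
  expect_equal(parsed$footwear, "shod")
  expect_equal(parsed$feature_id, "ar_coeff_7_maxlag_10")
  expect_equal(render_feature_name(parsed$zone, parsed$measurement,
                                   parsed$footwear, parsed$feature_id), nm)
  expect_error(render_feature_name("a__b", "m", "f", "id"), "__")
  expect_error(parse_feature_names("only__three__parts"), "unparseable")
})

test_that("the feature table has the configured shape and is deterministic", {
  demo <- demo_pipeline()
  ft <- demo$features
  bank <- attr(ft, "bank")
  lens <- vapply(demo$signals$references, function(r) r$length, integer(1))
  expect_equal(ncol(ft) - 2L, expected_feature_count(bank, lens))
  expect_equal(nrow(ft), 14)
  expect_false(anyNA(ft))

  # deterministic reconstruction
  ft2 <- build_feature_table(demo$signals, demo$cohort$profiles, bank)
  expect_identical(as.data.frame(ft), as.data.frame(ft2))

  # person characteristics present and label encoded 0/1
  expect_true(all(person_cols <- paste0(
    "person__characteristic__na__",
    c("sex", "height", "weight", "bmi", "shoe_size")) %in% names(ft)))
  expect_true(all(ft$injured %in% 0:1))
})

test_that("identical subjects produce identical feature rows; gaps are rejected", {
  demo <- demo_pipeline()
  sig <- demo$signals
  twin <- sig$signals[sig$signals$subject_id == "S001", ]
  twin$subject_id <- "S000"
  twin_set <- sig
  twin_set$signals <- dplyr::bind_rows(twin, sig$signals)
  prof <- demo$cohort$profiles
  twin_prof <- prof[prof$subject_id == "S001", ]
  twin_prof$subject_id <- "S000"
  ft <- build_feature_table(twin_set, dplyr::bind_rows(twin_prof, prof),
                            feature_bank(fft_k_max = 3))
  a <- as.numeric(ft[ft$subject_id == "S000", -1])
  b <- as.numeric(ft[ft$subject_id == "S001", -1])
  expect_identical(a, b)

  # a missing zone for one subject is an inventory error
  broken <- sig
  drop <- which(broken$signals$subject_id == "S002" &
                  broken$signals$zone == "midfoot")[1]
  broken$signals <- broken$signals[-drop, ]
  expect_error(build_feature_table(broken, prof, feature_bank(fft_k_max = 3)),
               "inventory")
})
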