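test_that("mutual information matches hand-computed histogram values", {
  # four equally frequent distinct values, x = y -> MI = ln 4
  x <- rep(c(0, 1, 2, 3), each = 8)
  expect_equal(mutual_information(x, x), log(4), tolerance = 1e-12)
  # degenerate marginal
  expect_equal(mutual_information(rep(5, 10), rnorm(10)), 0)
  # exactly factorizing joint
  expect_equal(mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_error(mutual_information(1:4, 1:5), "equal length")
})

test_that("mutual information is symmetric, nonnegative, and agrees with the pure-R oracle", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(10:150, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                c(rep(0, n %/% 2), runif(n - n %/% 2)),
                round(rnorm(n), 1))   # heavy ties
    y <- x + rnorm(n, 0, sample(c(0.01, 0.5, 2), 1))
    expect_equal(mutual_information(x, y), oracle_mi(x, y), tolerance = 1e-10)
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-10)
    expect_gte(mutual_information(x, y), 0)
  }
})

test_that("the reference is the longest run trial, ties broken deterministically", {
  mk <- function(sid, tr, n, fw = "barefoot", foot = "left") {
    tibble::tibble(subject_id = sid, footwear = fw, gait = "run",
                   foot = foot, trial_index = tr,
                   measurement = "mean_pressure", zone = "toe_1",
                   n = n, values = list(seq_len(n) * 1.0))
  }
  trials <- dplyr::bind_rows(mk("a", 1, 50), mk("a", 2, 55), mk("b", 1, 53))
  ref <- select_reference(trials, "barefoot")
  expect_equal(ref$length, 55)
  expect_equal(ref$subject_id, "a")

  same <- dplyr::bind_rows(mk("b", 2, 60), mk("a", 3, 60), mk("a", 1, 60))
  tie <- select_reference(same, "barefoot")
  expect_equal(tie$subject_id, "a")   # lowest (subject_id, trial_index)
  expect_equal(tie$trial_index, 1)

  expect_error(select_reference(trials, "shod"), "no run trials")
})

test_that("alignment returns the exhaustive-enumeration optimum", {
  # identity case
  ref <- c(0, 1, 4, 9, 4, 1, 0)
  a <- align_trial(ref, ref)
  expect_equal(a$left_pad, 0L)
  expect_equal(a$right_pad, 0L)
  expect_equal(a$padded, ref)

  # recovered offset equals the nonzero segment's original position
  seg <- c(1, 4, 9, 4, 1)
  a <- align_trial(seg, c(0, 0, seg, 0))
  expect_equal(a$left_pad, 2L)

  expect_error(align_trial(1:10, 1:5), "longer than reference")

  set.seed(8)
  for (i in 1:30) {
    L <- sample(20:80, 1)
    n <- sample(5:L, 1)
    values <- rnorm(n)
    reference <- rnorm(L)
    a <- align_trial(values, reference)
    o <- oracle_align(values, reference)
    expect_equal(a$left_pad, o$left_pad)
    expect_equal(a$mi, o$mi, tolerance = 1e-10)
    # structural invariants
    expect_equal(a$left_pad + a$right_pad + n, L)
    expect_equal(a$padded[(a$left_pad + 1):(a$left_pad + n)], values)
    expect_equal(sort(a$padded[a$padded != 0]), sort(values[values != 0]))
  }
})

test_that("aggregation is the pointwise mean of aligned trials", {
  v <- c(1, 2, 3, 4)
  expect_equal(aggregate_trials(list(v, v, v)), v)
  expect_equal(aggregate_trials(list(v, rep(0, 4))), v / 2)
  expect_error(aggregate_trials(list()), "no trials")
  expect_error(aggregate_trials(list(1:3, 1:4)), "one length")
})

test_that("scale normalisation divides by the walking maximum and preserves ratios", {
  signals <- tibble::tibble(
    subject_id = c("a", "a", "b"),
    footwear = "barefoot",
    measurement = c("peak_pressure", "mean_force", "peak_pressure"),
    zone = c("toe_1", "toe_1", "toe_1"),
    n = 3L,
    values = list(c(400, 200, 100), c(40, 20, 10), c(800, 400, 200))
  )
  sf <- tibble::tibble(subject_id = c("a", "b"), scale_factor = c(800, 1600))
  out <- normalize_scale(signals, sf)
  expect_equal(out$values[[1]], c(0.5, 0.25, 0.125))
  # ratios between signals of one subject are unchanged
  expect_equal(out$values[[1]] / out$values[[2]],
               signals$values[[1]] / signals$values[[2]])
  # proportional subjects end up with identical normalized signals
  expect_equal(out$values[[1]], out$values[[3]])
  # scale factor 1 is the identity
  id <- normalize_scale(signals,
                        tibble::tibble(subject_id = c("a", "b"),
                                       scale_factor = c(1, 1)))
  expect_equal(id$values, signals$values)
  # vertical force keeps its raw scale
  vf <- signals
  vf$measurement <- "vertical_force"
  expect_equal(normalize_scale(vf, sf)$values, vf$values)

  expect_error(
    normalize_scale(signals,
                    tibble::tibble(subject_id = "a", scale_factor = 800)),
    "missing walking data")
})

test_that("the preprocessing stage yields one normalized signal set per subject", {
  demo <- demo_pipeline()
  sig <- demo$signals
  n_sub <- length(unique(sig$signals$subject_id))
  expect_equal(nrow(sig$signals), n_sub * 62)
  # every signal has its footwear's reference length
  for (fw in c("barefoot", "shod")) {
    rows <- sig$signals[sig$signals$footwear == fw, ]
    expect_true(all(lengths(rows$values) == sig$references[[fw]]$length))
  }
  expect_true(all(sig$scale_factors$scale_factor > 0))
  # padding bookkeeping holds for every aligned trial
  run <- dplyr::filter(demo$cohort$trials, .data$gait == "run")
  al <- dplyr::left_join(
    sig$alignment, run,
    by = c("subject_id", "footwear", "foot", "trial_index", "measurement",
           "zone"))
  ref_len <- vapply(sig$references, function(r) r$length, integer(1))
  expect_equal(al$left_pad + al$right_pad + al$n,
               unname(ref_len[al$footwear]))
  expect_true(all(al$mi >= 0))
})
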