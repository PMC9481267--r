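test_that("subject profiles follow the class-specific anthropometrics", {
  set.seed(7)
  cfg <- cohort_config(n_subjects = 10)
  profs <- dplyr::bind_rows(lapply(1:4000, function(i) {
    sample_subject_profile(cfg, sprintf("P%04d", i))
  }))
  healthy <- profs[!profs$injured, ]
  injured <- profs[profs$injured, ]

  expect_equal(mean(healthy$height), 175.69, tolerance = 0.005)
  expect_equal(mean(healthy$weight), 68.65, tolerance = 0.01)
  expect_equal(sd(healthy$height), 8.23, tolerance = 0.05)
  expect_equal(mean(injured$height), 177.70, tolerance = 0.005)
  expect_equal(mean(injured$weight), 69.75, tolerance = 0.01)
  # injured fraction matches 35/155 and sex mix is class-specific
  expect_equal(nrow(injured) / nrow(profs), 35 / 155, tolerance = 0.1)
  expect_equal(mean(healthy$sex == "male"), 83 / 120, tolerance = 0.05)
  expect_equal(mean(injured$sex == "male"), 26 / 35, tolerance = 0.08)
  # bmi is derived, not drawn
  expect_equal(profs$bmi, profs$weight / (profs$height / 100)^2)
})

test_that("trial construction satisfies the conservation invariants exactly", {
  cohort <- demo_pipeline()$cohort
  tpl <- default_zone_templates()
  area <- stats::setNames(tpl$area, tpl$zone)
  footfalls <- cohort$trials |>
    dplyr::filter(.data$gait == "run") |>
    dplyr::group_by(.data$subject_id, .data$footwear, .data$foot,
                    .data$trial_index) |>
    dplyr::group_split()
  for (ff in footfalls[seq(1, length(footfalls), by = 7)]) {
    mp <- ff$values[ff$measurement == "mean_pressure"]
    names(mp) <- ff$zone[ff$measurement == "mean_pressure"]
    mf <- ff$values[ff$measurement == "mean_force"]
    names(mf) <- ff$zone[ff$measurement == "mean_force"]
    pk <- ff$values[ff$measurement == "peak_pressure"]
    names(pk) <- ff$zone[ff$measurement == "peak_pressure"]
    vf <- ff$values[ff$measurement == "vertical_force"][[1]]
    for (z in names(mp)) {
      expect_identical(mf[[z]], mp[[z]] * area[[z]])   # mean force exact
      expect_true(all(pk[[z]] >= mp[[z]]))             # peak >= mean
      expect_true(all(mp[[z]] >= 0))
    }
    # vertical force = sum of zone mean forces, exactly (same summation order)
    acc <- mf[[tpl$zone[1]]]
    for (z in tpl$zone[-1]) acc <- acc + mf[[z]]
    expect_identical(vf, acc)
  }
})

test_that("zone activation follows the heel-to-toe roll-off", {
  cohort <- demo_pipeline()$cohort
  ff <- cohort$trials |>
    dplyr::filter(.data$subject_id == "S001", .data$gait == "run",
                  .data$footwear == "barefoot", .data$foot == "left",
                  .data$trial_index == 1, .data$measurement == "mean_pressure")
  first_active <- vapply(ff$values, function(v) which(v > 0)[1], numeric(1))
  names(first_active) <- ff$zone
  expect_lt(first_active[["medial_heel"]], first_active[["midfoot"]])
  expect_lt(first_active[["midfoot"]], first_active[["metatarsal_3"]])
  expect_lt(first_active[["metatarsal_3"]], first_active[["toe_1"]])
})

test_that("cohort generation is reproducible and seed-sensitive", {
  cfg <- cohort_config(n_subjects = 5, seed = 31, injured_fraction = 0.4)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$trials$values, b$trials$values)
  expect_identical(a$profiles, b$profiles)

  cfg2 <- cohort_config(n_subjects = 5, seed = 32, injured_fraction = 0.4)
  c <- simulate_cohort(cfg2)
  expect_false(identical(a$trials$n, c$trials$n))   # lengths differ somewhere
})

test_that("the acquisition protocol produces the expected trial counts", {
  cohort <- simulate_cohort(cohort_config(n_subjects = 10, seed = 3))
  run_footfalls <- cohort$trials |>
    dplyr::filter(.data$gait == "run") |>
    dplyr::distinct(.data$subject_id, .data$footwear, .data$foot,
                    .data$trial_index)
  expect_equal(nrow(run_footfalls), 10 * 5 * 2 * 2)
  walk <- dplyr::filter(cohort$trials, .data$gait == "walk")
  expect_true(all(walk$footwear == "barefoot"))
  expect_true(all(walk$measurement == "vertical_force"))
  expect_equal(nrow(walk), 10 * 5 * 2)
  # trial lengths vary across trials
  expect_gt(length(unique(run_footfalls_n <- dplyr::filter(
    cohort$trials, .data$gait == "run")$n)), 3)
})

test_that("a null effect leaves injured and healthy forefoot loading indistinguishable", {
  set.seed(11)
  cfg <- cohort_config(n_subjects = 10, effect_size = 0,
                       injured_fraction = 0.5)
  peak_max <- function(profile) {
    tr <- simulate_trial(profile, "barefoot", "run", "left", 1, cfg)
    fore <- tr$measurement == "peak_pressure" & tr$zone %in% forefoot_zones()
    # scale-free summary: forefoot peak relative to body weight
    max(unlist(tr$values[fore])) / profile$weight
  }
  profs <- dplyr::bind_rows(lapply(1:200, function(i) {
    sample_subject_profile(cfg, sprintf("P%03d", i))
  }))
  vals <- vapply(seq_len(nrow(profs)), function(i) peak_max(profs[i, ]),
                 numeric(1))
  p <- stats::t.test(vals[profs$injured], vals[!profs$injured])$p.value
  expect_gt(p, 0.001)
})

test_that("the injured-vs-healthy forefoot gap grows monotonically with the effect size", {
  base <- cohort_config(n_subjects = 10, injured_fraction = 0.5)
  set.seed(21)
  profs <- dplyr::bind_rows(lapply(1:120, function(i) {
    sample_subject_profile(base, sprintf("P%03d", i))
  }))
  gap <- function(delta) {
    cfg <- cohort_config(n_subjects = 10, effect_size = delta,
                         injured_fraction = 0.5)
    set.seed(99)   # same trial noise for every delta
    vals <- vapply(seq_len(nrow(profs)), function(i) {
      tr <- simulate_trial(profs[i, ], "barefoot", "run", "left", 1, cfg)
      fore <- tr$measurement == "peak_pressure" & tr$zone %in% forefoot_zones()
      max(unlist(tr$values[fore])) / profs$weight[i]
    }, numeric(1))
    mean(vals[profs$injured]) - mean(vals[!profs$injured])
  }
  gaps <- vapply(c(0, 0.15, 0.3), gap, numeric(1))
  expect_lt(gaps[1], gaps[2])
  expect_lt(gaps[2], gaps[3])
})

test_that("degenerate configurations fail fast", {
  expect_error(cohort_config(injured_fraction = 0), "single-class")
  expect_error(cohort_config(injured_fraction = 1), "single-class")
  expect_error(cohort_config(n_subjects = 1), "n_subjects")
  expect_error(cohort_config(effect_size = -0.1), "effect_size")
  # sampled single-class cohort (tiny n, tiny fraction) errors explicitly
  expect_error(
    simulate_cohort(cohort_config(n_subjects = 2, injured_fraction = 1e-6,
                                  seed = 1)),
    "degenerate cohort")
  # missing zone template
  tpl <- default_zone_templates()[-1, ]
  expect_error(cohort_config(templates = tpl), "missing")
})

test_that("the trial store round-trips through its CSV/YAML artifacts", {
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(cohort_config(n_subjects = 4, seed = 11,
                                          injured_fraction = 0.5))
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(
    dir, c("trials.csv", "profiles.csv", "roster.csv", "config.yaml",
           "meta.json")))))
  back <- read_cohort(dir)
  key <- c("subject_id", "footwear", "gait", "foot", "trial_index",
           "measurement", "zone")
  a <- dplyr::arrange(cohort$trials, dplyr::across(dplyr::all_of(key)))
  b <- dplyr::arrange(back$trials, dplyr::across(dplyr::all_of(key)))
  expect_equal(a$values, b$values)
  expect_equal(back$config$effect_size, cohort$config$effect_size)
  expect_equal(back$profiles$zone_amp, cohort$profiles$zone_amp)
})
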