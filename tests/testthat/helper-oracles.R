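# Independent oracles, kept deliberately naive and separate from the
# package's implementation paths.

# Pure-R 2D-histogram mutual information (nats), same binning convention:
# n_bins equal-width bins spanning each signal's own [min, max], top edge
# closed.
oracle_mi <- function(x, y, n_bins = 256) {
  stopifnot(length(x) == length(y))
  bin <- function(v) {
    lo <- min(v)
    hi <- max(v)
    if (hi <= lo) return(rep(1L, length(v)))
    pmin(pmax(floor((v - lo) / (hi - lo) * n_bins), 0), n_bins - 1) + 1L
  }
  bx <- bin(x)
  by <- bin(y)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
      }
    }
  }
  as.numeric(mi)
}

# Exhaustive enumeration over every (left, right) zero padding.
oracle_align <- function(values, reference, n_bins = 256) {
  P <- length(reference) - length(values)
  stopifnot(P >= 0)
  mis <- vapply(0:P, function(l) {
    oracle_mi(c(rep(0, l), values, rep(0, P - l)), reference, n_bins)
  }, numeric(1))
  best <- which.max(mis)   # first max = smallest left pad
  list(left_pad = best - 1L, mi = mis[best])
}

# Brute-force AUC: count positive-negative pairs, ties worth 1/2.
oracle_auc <- function(labels, probabilities) {
  pos <- probabilities[labels == 1]
  neg <- probabilities[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Direct O(n^2) evaluation of the DFT sum A_k = sum_m X_m exp(-2*pi*i*m*k/n).
oracle_dft <- function(x, k) {
  n <- length(x)
  m <- 0:(n - 1)
  sum(x * exp(-2i * pi * m * k / n))
}

# Zero-flanked reference with a sharp-onset stance-like bump; the trial is
# the full nonzero segment plus mild additive noise. Returns the true left
# offset alongside.
make_alignment_case <- function(ref_len, seg_len, noise_sd = 0.02) {
  l_true <- sample(0:(ref_len - seg_len), 1)
  u <- seq(0, 1, length.out = seg_len)
  amp <- runif(1, 0.5, 2)
  bump <- (0.15 + 0.85 * sin(pi * u)^2) * amp
  list(
    reference = c(rep(0, l_true), bump, rep(0, ref_len - seg_len - l_true)),
    trial = bump + rnorm(seg_len, 0, noise_sd * amp),
    left_true = l_true
  )
}

# Shared small end-to-end fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

demo_pipeline <- function() {
  if (is.null(.fixtures$demo)) {
    cohort <- simulate_cohort(cohort_config(n_subjects = 14, seed = 42,
                                            injured_fraction = 0.35))
    signals <- preprocess_trials(cohort)
    features <- build_feature_table(signals, cohort$profiles,
                                    feature_bank(fft_k_max = 15))
    .fixtures$demo <- list(cohort = cohort, signals = signals,
                           features = features)
  }
  .fixtures$demo
}

# A small synthetic feature table with pipeline-style names: `n_signal`
# informative columns correlated with the label plus pure-noise columns.
toy_feature_table <- function(n = 30, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  tibble::tibble(
    subject_id = sprintf("T%02d", seq_len(n)),
    injured = y,
    toe_1__peak_pressure__shod__maximum = y + rnorm(n, 0, 0.3),
    metatarsal_2__peak_pressure__barefoot__maximum = y + rnorm(n, 0, 0.4),
    toes_2_5__mean_pressure__shod__abs_energy = y + rnorm(n, 0, 0.5),
    midfoot__mean_force__barefoot__mean = rnorm(n),
    medial_heel__peak_pressure__shod__minimum = rnorm(n),
    whole_foot__vertical_force__shod__maximum = rep(1, n),  # constant
    person__characteristic__na__height = rnorm(n, 176, 8)
  )
}
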