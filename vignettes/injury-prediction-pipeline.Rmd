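---
title: "Predicting lower-extremity overuse injuries from plantar pressure: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lower-extremity overuse injuries from plantar pressure: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantarisk)
```

## The problem

Lower-extremity overuse injuries develop gradually under repetitive load.
Pressure plates offer a cheap, field-deployable window on running
biomechanics: a single barefoot/shod running assessment yields, per
footfall, the whole-foot vertical force and three zone-resolved series
(peak pressure, mean pressure, mean force) over ten anatomical foot zones
(hallux, toes 2–5, metatarsal heads 1–5, midfoot, medial and lateral heel)
sampled at 250 Hz. `plantarisk` implements a complete, leakage-safe
pipeline that turns such trials into a per-subject injury-risk probability
and attributes the predictive signal to foot areas, measurement types and
footwear conditions.

The pipeline has five stages:

1. **Alignment.** Footfalls differ in stance duration. Every running trial
   is zero-padded to the length of the longest running trial of its
   footwear condition (the *reference*), choosing among all
   `(left, right)` zero splits the one that maximises the 2D-histogram
   mutual information (MI, natural log, 256 bins per axis) between the
   padded trial and the reference's series of the same zone and
   measurement. Padding, unlike resampling or time-warping, leaves all
   within-trial temporal structure intact.
2. **Aggregation and scale normalisation.** A subject's aligned trials are
   averaged pointwise into one signal per (zone, measurement, footwear).
   Pressure and force signals are then divided by the subject's maximum
   barefoot-*walking* vertical force, removing body-weight and speed
   differences while preserving the relative scale of the zones.
3. **Feature construction.** Each of the 62 signals per subject (10 zones
   × 3 measurements × 2 footwear + whole-foot vertical force × 2 footwear)
   is summarised by a configurable feature bank; person characteristics
   (sex, height, weight, BMI, shoe size) complete the row.
4. **Selection and model.** Per cross-validation fold: features are ranked
   by the two-class ANOVA F statistic; the number of features `k` is chosen
   from {5, 10, 15, 20, 25} by training AUC; an L1-penalised logistic
   regression on the fold-standardized top-`k` features provides a second,
   embedded selection stage (coefficients shrink to exactly zero).
5. **Evaluation and attribution.** Leave-one-subject-out cross-validation
   pools the N out-of-fold probabilities into one AUC (ranking quality) and
   one Brier score (calibration, $BS = N^{-1}\sum_i (p_i - y_i)^2$).
   Group-exclusion analysis reruns the pipeline with all features of one
   group (a foot area, a measurement type, or a footwear condition)
   removed and reports the score change.

## Why the whole pipeline sits inside the fold

Selection-induced leakage is the central methodological hazard at this
sample size: thousands of candidate features against ~100 subjects. Both
selection stages and the feature standardization therefore run on the
N−1 training subjects of each fold only. `run_loocv(..., leaky = TRUE)`
deliberately commits the classic mistake — ranking and choosing features
once on the full table before splitting — purely to quantify the damage:
on a null cohort (no injury effect anywhere) the leakage-safe estimate sits
at chance while the leaky one typically exceeds 0.9 AUC. That contrast is a
regression test in `tests/testthat/test-acceptance.R`.

## Mutual-information alignment: numerical behaviour

MI is estimated from the joint histogram of paired samples on a 256 × 256
grid, each axis spanning that signal's own [min, max] with a closed top
edge; empty cells contribute nothing; the result is in nats (the base is a
free convention — no published MI value is treated as comparable). The
padded zeros are part of the padded signal's histogram.

Two numerical choices matter:

* **Tie-breaking.** MI ties across paddings are broken toward the smallest
  left pad; reference-length ties toward the lowest
  (subject id, trial index, foot). Both rules make reruns bit-identical.
* **What the objective can and cannot localise.** With ~60–120 samples in
  256 bins, most nonzero values occupy singleton bins, and any x-bin seen
  only once contributes zero conditional entropy regardless of where it
  lands. The discriminating mass is the repeated zero bin: misalignment
  forces padded zeros onto nonzero reference samples and spreads that row
  of the joint histogram. Alignment is therefore sharp for signals with an
  abrupt onset/offset (foot strike and toe-off produce exactly that), and
  soft for smooth, slowly vanishing tails. The offset-recovery suite
  constructs zero-flanked references with sharp-onset stance-like bumps
  and recovers the true offset in ≥ 95% of noisy cases while agreeing with
  exhaustive enumeration in 100%.

The padding search is implemented in C++ (the padded signal's histogram
range and both marginals are invariant across pad positions, so only the
joint counts are recomputed per candidate); a pure-R brute-force oracle in
the test helpers checks every tested instance.

## The feature bank

The bank approximates, at a deliberately smaller and fully configurable
scale, the exhaustive default sets of automated time-series featurisation
tools (tens of thousands of features); reproducing any exact default list
is a non-goal. Defaults per signal:

| family | features |
|---|---|
| moments | maximum, minimum, mean, SD, skewness, excess kurtosis |
| energy/shape | absolute energy $\sum x^2$, count of strict local maxima |
| trend | least-squares slope and intercept against sample index |
| autocorrelation | lags 1–10 |
| FFT | angle and magnitude of $A_k = \sum_m X_m e^{-2\pi i mk/n}$, k = 0…min(99, n−1) |
| autoregression | $\phi_0 \ldots \phi_{10}$ of $X_t = \phi_0 + \sum_i \phi_i X_{t-i} + \epsilon_t$ |

FFT coefficient angles and AR coefficients are implemented exactly as
defined above because they are the two feature families the original
analysis found predictive; `phi_0` is the intercept, so "the 7th AR
coefficient with maximum lag 10" is the lag-7 weight. The AR fit is
conditional least squares (OLS of $X_t$ on an intercept and the lagged
values), matching the standard implementation such toolchains delegate to.
The angle of a numerically zero FFT coefficient (modulus < 1e−12) is
defined as 0 to avoid platform-dependent `atan2(0, 0)`. A feature that is
undefined for some subject (e.g. AR on a constant signal) becomes `NA` and
is imputed with the training-fold median inside the cross-validation loop,
never from the full table.

With the default bank and reference lengths around 60–70 samples this
yields roughly 10,000 feature columns — large enough that selection, not
the classifier, dominates the statistical behaviour, which is the regime
the pipeline is designed for.

## Model and tunables

| parameter | default | meaning |
|---|---|---|
| `grid` | {5, 10, 15, 20, 25} | candidate feature counts per fold; bounded above by the 10% rule for ~155 subjects, in steps of 5 |
| `C` | 1 | inverse L1 penalty strength; the fixed penalty is λ = 1/(nC) |
| `max_iter` | 100 | per-penalty cap on coordinate-descent passes; a warning reports a stop at the cap |
| `n_bins` | 256 | MI histogram resolution |
| `budget` | floor(N/10) | fixed feature count in the group-exclusion analysis (15 at N = 155; truncation, not rounding, reproduces the published budget) |
| `threshold` | 0.10 | minimum fold fraction for the feature-occurrence report (inclusive) |

Features are z-scored with training-fold means/SDs before the L1 fit: the
bank mixes scales (angles in radians, energies in squared normalized
force), and a shared penalty is only meaningful on a common scale. The
solver is glmnet's coordinate descent along a short decreasing penalty
path ending exactly at λ; a univariate fit is padded with a void column
(the solver requires two) whose coefficient is discarded. "Occurrence" of
a feature requires surviving *both* stages in a fold: chosen by the filter
and carrying a nonzero L1 weight.

The group-exclusion deltas are oriented so that positive means the
excluded model performed *better* (ΔAUC = excluded − baseline;
ΔBrier = baseline − excluded, Brier being a loss). Groups are ranked
within each kind by ΔAUC, ties by ΔBrier; rank 1 is the group whose
removal hurts most. A group never selected in either run leaves every fold
untouched and scores exactly 0.

## The synthetic cohort

No public pressure-plate cohort with injury follow-up exists, so the
package ships a generator that reproduces the *statistical structure* the
pipeline relies on, not running biomechanics:

* **Protocol.** Five footfalls per foot per condition: barefoot running,
  shod running, barefoot walking (walking is consumed only as the
  normalisation source and carries the whole-foot vertical force;
  `walk_full_measurements = TRUE` generates the zone series too).
* **Anthropometrics** are drawn from class-specific normals matching the
  study population (healthy 175.69 ± 8.23 cm, 68.65 ± 9.00 kg; injured
  177.70 ± 8.04 cm, 69.75 ± 8.63 kg; sex mix 83/120 and 26/35 male;
  injured fraction 35/155), with BMI derived and EU shoe size regressed on
  height.
* **Signal model.** Each zone's mean pressure is a squared-sine bump on
  its activation window (heels 0–40%, midfoot 20–60%, metatarsal heads
  30–90%, toes 55–100% of stance — a heel-to-toe roll-off). Mean force is
  mean pressure × zone area *exactly*; the whole-foot vertical force is
  the sum of the zone mean forces *exactly*; peak pressure is mean
  pressure × a noisy per-zone peak factor bounded below by 1. A per-
  subject, per-gait scale calibrates the noise-free template so the
  vertical-force peak hits 1.1 × body weight walking and 2.5 × running.
* **Stance durations** run 0.22 ± 0.02 s, walk 0.70 ± 0.05 s (≈55 and 175
  samples at 250 Hz) — plausible values; none are published.
* **Variability.** Log-normal per-subject zone-amplitude (SD 0.15) and
  peak-factor (SD 0.10) multipliers give each subject a persistent loading
  style; per-trial amplitude noise (SD 0.08) and per-sample peak noise
  (SD 0.05) add within-subject scatter; stance duration varies per trial.
  Shod trials reuse the barefoot template with a 0.9 amplitude attenuation
  and independent noise, so the two footwear conditions carry partially
  redundant information. The raw signals' true noise structure is
  unpublished; these levels are free parameters chosen once as realistic.
* **Injury effect.** The generator's contract is an effect *concentrated
  on forefoot peak pressures*: by default `effect_size` δ multiplies the
  injured subjects' forefoot peak factors by (1 + δ), during running only.
  Two documented alternatives exist because the design was genuinely open:
  `effect_measurement = "amplitude"` scales the forefoot mean-pressure
  bump instead (the effect then propagates into mean pressure, mean force
  and vertical force), and `effect_gait = "all"` extends it to walking.
  The defaults keep the walking-based normaliser label-free and make the
  attribution analysis well-posed (a known ground truth: the peak-pressure
  group should rank first). `timing_shift` optionally delays the injured
  forefoot activation window.

Left and right feet are simulated independently and pooled into one
average per (zone, measurement, footwear) during preprocessing — the
published feature tables never separate feet — with `pool_feet = FALSE`
available. MI is maximised per (measurement, zone) series independently.

**What passing tests on this cohort do and do not show.** They show the
machinery is correct: conservation laws hold exactly, alignment matches
exhaustive enumeration, selection never sees the held-out subject, a
planted effect of realistic size is detected and attributed to the right
group, and a null effect yields chance-level AUC. They do not show that
real injuries are predictable at any particular AUC: the generator's
subjects differ from real runners (no gait pathologies, no footwear
heterogeneity, a single known effect direction), so published headline
numbers on the real cohort are not reproduction targets here.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full pipeline at 60
subjects (null cohort) and 80 subjects (effect cohort, δ = 0.3), with
5-seed replication for the signal-recovery property; parameter-recovery
suites use 200 alignment cases and AR series of length 5000. These sizes
make the stochastic checks stable while keeping a complete run in the
minutes range.

## Known limitations

* The generator is statistical plumbing, not biomechanics: no
  double-hump vertical-force profile, no medio-lateral roll-over coupling,
  no footwear models, adult anthropometry only.
* Histogram MI on short trials localises alignment through the padded-zero
  mass (see above); signals without a sharp onset align softly. This is a
  property of the published method itself, preserved deliberately.
* With one test subject per fold, AUC/Brier are only defined on the pooled
  out-of-fold probabilities; per-fold metrics do not exist.
* LOOCV on null data is slightly pessimistic (the held-out subject's class
  is underrepresented in its own training fold), so chance-level AUC
  estimates scatter below 0.5 as often as above.
* The exact univariate filter and penalty strength of the original
  toolchain are unpublished ("defaults"); ANOVA F and C = 1 are this
  package's documented choices, exposed in the configuration.

## A worked call

```{r example, eval = FALSE}
cfg <- experiment_config(
  cohort = cohort_config(n_subjects = 40, effect_size = 0.3),
  out_dir = "plantarisk-run",
  seed = 1
)
res <- run_experiment(cfg)
glance(res$loocv)
autoplot(res$loocv)      # pooled ROC curve
autoplot(res$impact)     # group-exclusion deltas
```

Every artifact (trial store, aligned-signal cache, feature table,
predictions, metrics, group-impact and occurrence reports, manifest) is
plain text and byte-identical across reruns of the same configuration.
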