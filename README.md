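# plantarisk

Predicting lower-extremity overuse injuries from pressure-plate running
trials, and attributing the prediction to foot areas, measurement types and
footwear conditions.

## Who this is for

Sports-medicine and biomechanics groups that screen runners with a plantar
pressure plate (whole-foot vertical force plus zone-resolved peak pressure,
mean pressure and mean force over the ten anatomical foot zones, sampled at
250 Hz) and want a reproducible, leakage-safe machine-learning pipeline
from raw footfall trials to a per-subject injury-risk probability — plus a
synthetic cohort generator so the whole pipeline can be exercised and
tested without access to any clinical data.

## The method

For subject *i* with binary outcome *y<sub>i</sub>* (1 = lower-extremity
overuse injury within follow-up) and out-of-fold predicted probability
*p<sub>i</sub>*:

1. **Alignment.** Every running trial is zero-padded to the length of the
   longest running trial of its footwear condition; among all left/right
   zero splits, the pipeline keeps the one maximising the 2D-histogram
   mutual information (256 bins per axis)

   MI(x, y) = Σ<sub>ij</sub> p̂(i, j) ln [ p̂(i, j) / (p̂<sub>x</sub>(i) p̂<sub>y</sub>(j)) ]

   between the padded trial and the reference. No stretching or
   resampling — within-trial timing is preserved.
2. **Normalisation.** Trials are averaged per subject and divided by the
   subject's maximum barefoot-walking vertical force.
3. **Features.** A configurable bank per signal; the two families the
   method leans on are the DFT coefficients
   A<sub>k</sub> = Σ<sub>m</sub> X<sub>m</sub> e<sup>−2πimk/n</sup>
   (angle and magnitude) and the AR(10) coefficients of
   X<sub>t</sub> = φ<sub>0</sub> + Σ<sub>i</sub> φ<sub>i</sub> X<sub>t−i</sub> + ε<sub>t</sub>.
4. **Selection + model, per fold.** ANOVA-F ranking → k ∈ {5, 10, 15, 20,
   25} chosen by training AUC → L1-penalised logistic regression on
   fold-standardized features (λ = 1/(nC), C = 1).
5. **Evaluation.** Leave-one-subject-out cross-validation; pooled AUC and
   Brier score BS = N<sup>−1</sup> Σ (p<sub>i</sub> − y<sub>i</sub>)².
   Group-exclusion analysis reruns the pipeline without each feature group
   at a fixed 10%-rule budget (floor(N/10) features) and ranks groups by
   the AUC drop their removal causes.

All selection, standardization and imputation happen strictly inside each
training fold; `run_loocv(leaky = TRUE)` exists only to demonstrate how
badly selection-before-split inflates the estimate.

See `vignettes/injury-prediction-pipeline.Rmd` for the full methods
account, every tunable with its default, and what the synthetic cohort
does and does not emulate.

## Worked example

```r
library(plantarisk)

cfg <- experiment_config(
  cohort  = cohort_config(n_subjects = 40, effect_size = 0.3),
  out_dir = "plantarisk-run",
  seed    = 1
)
res <- run_experiment(cfg)
res$loocv
#> <loocv_result> 40 subjects
#>   AUC = 0.926 | Brier = 0.092
#>   k per fold: mean 20.2, median 20
#>   nonzero weights per fold: mean 4.0

dplyr::filter(res$impact, kind == "measurement")
#> # A tibble: 5 × 7
#>   kind         rank group                     delta_auc delta_brier   auc  brier
#>   <chr>       <int> <chr>                         <dbl>       <dbl> <dbl>  <dbl>
#> 1 measurement     1 peak_pressure                -0.502      -0.136 0.472 0.196
#> 2 measurement     2 mean_pressure                 0           0     0.974 0.0599
#> 3 measurement     3 mean_force                    0           0     0.974 0.0599
#> 4 measurement     4 vertical_force                0           0     0.974 0.0599
#> 5 measurement     5 general_person_character…     0           0     0.974 0.0599
```

What these numbers mean: the simulated cohort plants a 30% peak-pressure
increase on the injured subjects' forefoot during running. The
leave-one-out AUC of 0.926 says the pipeline ranks injured above healthy
subjects; the Brier score of 0.092 says the probabilities are well
calibrated. In the group-exclusion table, removing the peak-pressure
features collapses the AUC to chance (ΔAUC = −0.502, rank 1) while every
other measurement group leaves the predictions untouched (Δ = 0 exactly —
their features never survive selection): the analysis attributes the
signal to precisely the measurement that carries it. `autoplot(res$loocv)`
draws the pooled ROC curve, `autoplot(res$impact)` the Δ-AUC bars, and
`feature_occurrence(res$loocv)` lists the features that survive both
selection stages in ≥ 10% of folds.

All artifacts (trial store, aligned signals, feature table, predictions,
metrics, reports, manifest) are written as deterministic plain-text
CSV/JSON under `out_dir`. A thin command-line wrapper lives at
`inst/scripts/run_experiment.R`.

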