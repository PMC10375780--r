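# hdcohort

Longitudinal clinical cohorts in Huntington's disease (HD) — such as the
access-controlled Enroll-HD platform — are rich but hard to model: most
cells are "missing" for structural reasons (baseline-only forms,
change-only items, not-applicable questions), onset ages exist only when a
paired indicator says the symptom has begun, and each participant
contributes an irregular handful of roughly annual visits. `hdcohort` is a
tested, reusable R implementation of the full analysis workflow such data
calls for, aimed at biostatisticians and clinical-ML researchers working
with HD (or similarly shaped) registries:

1. **Synthetic cohorts with ground truth** — `generate_cohort()` emulates
   the Enroll-HD table layout (per-participant profile + per-visit table +
   variable catalog) with every missingness mechanism tagged, so every
   downstream stage is testable without restricted data.
2. **Rule-based pre-processing** — inclusion criteria (adult onset, CAG
   36-59), strict >69% missingness filtering, 4-sigma report-only outlier
   flags, derived variables (parent AAO; the CAG-age product
   `CAP = A (R - L) K`, L = 30, K = 6.27), deterministic inference of
   structural gaps (baseline copy, LOCF, conditional zeros, rater
   substitution for the age at onset), symptom-onset gating and one-hot
   encoding — all with per-cell provenance and an auditable log.
3. **A score-ordered imputation cascade** — per-variable 10-fold CV model
   selection (random forest / linear–logistic / kNN; R2 for continuous,
   weighted F1 otherwise), imputation from best- to worst-predicted
   variable with re-scoring on the augmented table, domain clipping and
   composite recomputation.
4. **Age-at-onset (AAO) prognosis** — the Langbehn exponential formula

   `AAO = 21.54 + exp(9.556 − 0.146 · CAG)`

   evaluated as-published and refit by nonlinear least squares, benchmarked
   against a registry of multivariate learners (linear, SVR, forest, kNN,
   MLP, three gradient-boosted variants) under a shared seeded fold
   partition, on narrow (41-56) and wide (36-59) CAG ranges.
5. **Driving-capability sequence models** — visits mapped to five annual
   slots, a masked, two-head GRU (current and next-year status) written in
   RcppArmadillo with exact BPTT, class weights `w_c = n / (C·n_c)`,
   leakage-free [-1, 1] scaling, an 18-point tuning grid, ROC operating
   points, ten-bin calibration bands and personalised trajectories.

## Worked example

```r
library(hdcohort)

sim    <- generate_cohort(generator_config(n_participants = 300, seed = 1))
cohort <- as_cohort_table(sim)
round(100 * completeness(cohort), 2)
#> [1] 76.13

pp <- preprocess(cohort)
round(100 * completeness(pp), 2)
#> [1] 98.48
```

Pre-processing lifted completeness from 76.1% to 98.5% purely by
deterministic rules: copying baseline-only forms forward, carrying
change-only items forward, zeroing not-applicable items, substituting the
rater's onset estimate, and dropping the one block whose missingness
exceeds the 69% threshold. The substitution is justified by its validation
report — the clinical and rater onset ages correlate at r = 0.933 overall
(n = 224 doubly observed participants; 0.93-0.95 within each rater
confidence level):

```r
attr(pp, "reports")$aao_substitution
#>   level       n     r         p
#> 1 overall   224 0.933 1.05e-100
#> 2 high      126 0.932 1.20e- 56
#> 3 low        35 0.954 7.10e- 19
#> 4 unknown    63 0.929 5.63e- 28
```

The remaining ~1.5% of cells are imputed by the cascade; the report shows,
per variable, the winning model family, whether the initial or the refit
round was kept, and the CV score it was imputed under (R2 or weighted F1):

```r
imp <- run_cascade(pp, seed = 1,
                   control = cascade_control(num_trees = 60, k_folds = 5))
head(imp$report[, c("variable", "dtype", "rank", "chosen_family",
                    "chosen_round", "final_score")], 5)
#>   variable   dtype rank      chosen_family chosen_round final_score
#> 1    dadhd boolean    1      random_forest      initial       0.918
#> 2    momhd boolean    2      random_forest        refit       0.977
#> 3  driving boolean    3      random_forest        refit       0.799
#> 4      ms3 ordinal    4 linear_or_logistic        refit       0.627
#> 5      ms2 ordinal    5 linear_or_logistic        refit       0.646
```

AAO prediction compares the formula against multivariate learners on the
fully imputed table:

```r
langbehn_predict(41)
#> [1] 57.05659   # years, at 41 CAG repeats

ds <- make_aao_dataset(imp$table, "wide_36_59")   # 200 diagnosed rows
ev <- evaluate_registry_cv(ds, k = 10, seed = 1)
rank_models(ev)                                    # benchmark-table shape
```

The driving stage reshapes the imputed table into a masked tensor, splits
participants 80/20 stratified by missing-visit count, scales features on
the training slots, and trains the GRU; `evaluate_driving()` returns AUC /
accuracy / F1 per head, ROC operating points and the confusion
percentages, `band_accuracy()` the calibration bands, and
`predict_trajectory()` a per-participant trajectory with a one-step-ahead
prediction. The one-config pipeline runs everything in order:

```r
run <- run_pipeline(pipeline_config(
  generator = generator_config(n_participants = 1000, seed = 1),
  seed = 1))
render_reports(run, dir = "reports")   # completeness, imputation scores,
                                       # AAO table, ROC/bands/trajectories
```

A thin command-line wrapper lives at `inst/scripts/hdcohort.R`.

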