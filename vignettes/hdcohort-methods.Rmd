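---
title: "Methods: cohort preprocessing, imputation and prognosis models in hdcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort preprocessing, imputation and prognosis models in hdcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hdcohort` implements an end-to-end analysis workflow for Enroll-HD-shaped
longitudinal Huntington's disease (HD) data: a synthetic-cohort generator
with known ground truth, rule-based pre-processing, a cross-validated
machine-learning imputation cascade, age-at-onset (AAO) prognosis
benchmarked against the Langbehn exponential formula, and a masked
recurrent (GRU) classifier of current and next-year driving capability.
This vignette records the models, the assumptions behind them, and the
design decisions taken where the problem was genuinely open.

## Why a synthetic cohort

The real Enroll-HD periodic datasets are access-controlled, so the package
ships a generator (`generate_cohort()`) that emulates the *structures* the
workflow has to handle rather than any particular release: CAG repeat
lengths in the adult HD-causing range (36-59), an exponential CAG-to-AAO
mean curve, one to five roughly annual visits with jitter and dropout, and
— crucially — the recording rules that create *structural* missingness:

* **baseline-only** forms (medical-history-like), recorded at the first
  visit only;
* **change-only** items (general-variables-II-like), recorded only when
  the value changes;
* **conditional** items gated by a trigger (smoking quantity items are
  empty, meaning zero, for never-smokers);
* **symptom onset/indicator pairs**, where an onset age exists only if the
  paired indicator records 1, is unknowable if the indicator is missing,
  and is "not applicable" if the indicator is 0;
* a **high-missingness block** (WPAI-like) sitting above the variable
  exclusion threshold;
* optional **MCAR** noise on the always-recorded clinical core.

Every synthetically missing cell is tagged with exactly one mechanism in
the ground-truth ledger (`truth$masked`), which is what makes the recovery
tests exact: with MCAR off, the pre-processing inference rules must
restore every baseline-only, change-only and conditional cell to its true
value, cell for cell.

### The generative AAO model

True AAO is `Langbehn(CAG) + family effect + covariate effects + noise`,
truncated below at 21 years by re-sampling (up to 100 attempts, then an
error), mirroring the adult-onset inclusion criterion. The family effect
(`family_effect_sd = 5` years) is shared between a participant and their
affected parent's onset age, so parent AAO carries predictive signal
beyond CAG — this is the signal the AAO benchmark has to detect.
Gender has zero true effect by default, so model comparisons can detect
inflation. Individual noise is `aao_noise_sd = 5` years; together the two
terms leave roughly 30% of AAO variance unexplained by CAG alone, in line
with the common observation that the repeat length explains about 70% of
onset variability. The rater's estimate of onset is truth plus noise with
`rater_noise_sd = 6` years, chosen so the clinical-vs-rater Pearson
correlation lands near 0.94, the adequacy level the substitution rule is
validated against.

The marginal CAG distribution is a geometric-like decay away from 41
(`0.75^|CAG - 41|`), a placeholder for the unknown cohort distribution; it
is configurable via `cag_weights` and nothing downstream depends on its
exact shape.

### Driving labels

Each visit's binary driving status is Bernoulli with probability
`sigmoid(-slope * (CAP_w - midpoint))`, where `CAP_w` is the Warner-scaled
CAG-age product (100 marks expected onset) — the package's one internal
definition of disease progression. The default slope (0.135 per CAP unit)
was calibrated once against the generator's own equations so that the
label-vs-probability AUC (`driving_separability()`) is about 0.9; that
ceiling is what the GRU experiment is judged against. The midpoint default
of 100 places the 50/50 driving odds at expected onset.

Visit counts come from a per-step dropout probability (default 0.3, mean
about 2.8 visits within the 1-5 window). This also keeps the baseline-only
block's missing fraction below the 69% exclusion threshold, as it is in
the real data, where the medical-history form survives variable filtering
and is then repaired by inference.

What the generator does **not** emulate: medication/comorbidity forms,
juvenile HD, multi-site effects, genetic modifiers, informative (MNAR)
dropout, or the clinical consistency between diagnosis timing and visit
age. Passing tests therefore demonstrate that the machinery is correct
under controlled conditions, not that the models transfer to real
Enroll-HD numbers.

## Pre-processing

`preprocess()` chains the sub-steps in a fixed order; each acts on a
cohort tibble that carries per-cell provenance and an append-only decision
log:

1. **Inclusion** (`select_cohort()`): drop participants with clinical or
   rater-estimated AAO below 21, or `caghigh` outside 36-59.
2. **Variable filtering** (`filter_variables()`): drop variables with
   missing fraction *strictly* above 0.69 (the threshold is a parameter;
   the comparison is strict because the rule is stated as "> 69%"), plus a
   configurable drop list with reason categories (redundant,
   used-in-derived, no-information, other).
3. **Outlier flagging** (`detect_numeric_outliers()`): report-only flags
   for continuous values strictly outside mean +/- 4 SD. Report-only
   because flagged values are for human review, and the boundary is strict
   ("outside the range"). Constant columns produce no flags; variables
   with fewer than two observations are skipped and listed.
4. **Derived variables** (`derive_variables()`): parent AAO is the younger
   recorded parental onset (the recorded one if only one parent's onset is
   known — the variable's definition extends naturally to that case), and
   the CAP score. The CAP constants are L = 30, K = 6.27. Two combine
   modes exist because the printed equation `A x (R - L) x K` conflicts
   with the cited Warner scaling in which CAP = 100 at expected onset
   (that requires dividing by a constant near 6.27, not multiplying).
   `multiply_as_printed` is the default; `divide_warner` is provided and
   used internally by the generator's progression model. Neither is
   asserted as "correct".
5. **Structural inference** (`infer_missing()`): baseline-only values copy
   forward from the first visit; change-only values are
   last-observation-carried-forward (never backwards: a later record can
   not inform an earlier visit); conditional variables with trigger 0
   become 0; missing clinical AAO takes the rater's estimate with
   provenance `inferred_rater`. The step is idempotent.
6. **Substitution validation** (`validate_aao_substitution()`): Pearson r
   between clinical and rater AAO on doubly-observed participants, overall
   and per confidence level, warning if r does not exceed 0.9.
7. **Symptom-onset filtering** (`filter_symptom_onsets()`): a pair is
   dropped when more than 20% of indicators record 0 or missing;
   otherwise participants with missing indicators are excluded and
   indicator-0 onset cells are marked `onset_not_applicable` — never
   imputed, because no assumption about an onset that has not happened is
   defensible. (An onset variable lacking a declared indicator cannot be
   recognised as such; the catalog declaration is the contract.)
8. **One-hot encoding** (`one_hot_encode()`), last, so the inference rules
   above operate on original nominal codes. A missing source value yields
   all-missing indicators: absence is not the same as all-negative.

Completeness (`completeness()`) is the fraction of non-missing cells over
catalog-covered columns of the participant-visit table, overall and per
form; the per-form fractions aggregate exactly (cell-weighted) to the
overall value. It can only decrease through explicit, logged drops.

## The imputation cascade

Remaining missing cells are imputed variable by variable
(`run_cascade()`). For each target the three candidate families — random
forest, linear/logistic regression, k-nearest-neighbours on standardized
predictors — are scored by 10-fold cross-validation on the rows where the
target is observed: mean fold R2 for continuous targets, weighted F1 for
ordinal (regression predictions rounded and clipped first) and
categorical targets. Predictors are the variables with no missing values
in the current table, so each completed imputation widens the predictor
set for later ones.

Variables are then imputed in descending initial-score order
(lexicographic name tiebreak; family ties prefer forest, then linear,
then kNN). At a variable's turn its families are re-scored on the
augmented table and the initial-round model is kept if it scored at least
as high. Re-scoring at the turn is outcome-equivalent to re-scoring every
remaining variable after every imputation (intermediate refits would
never be consulted) and reduces the cost from quadratic to linear in the
number of imputed variables.

Numerical choices: ordinal rounding uses round-half-to-even (base R's
`round()`), documented and tested; kNN uses k = 5 with predictors
standardized by training-fold moments; the forest has 100 trees; all
three live in `cascade_control()`. Random-forest prediction passes an
explicit seed so vote tie-breaking never touches the global RNG —
without it the cascade would not be bit-reproducible. Full one-hot blocks
are collinear with the intercept by construction; `lm`/`glm` pivot the
redundant columns, which is expected and harmless.

Composite scores (e.g. the total motor score) are never imputation
targets; they are recomputed as the sum of their components afterwards,
overwriting any recorded value — the recorded total of partially imputed
items is the one cell whose provenance is deliberately replaced. A
composite with a still-missing component stays missing and is logged.

Observed cells never change; only cells that are missing and not marked
`onset_not_applicable` receive values, tagged `imputed_ml`.

## AAO prognosis

`make_aao_dataset()` keeps one row per clinically diagnosed participant
(rows whose AAO came from rater substitution are discarded — the target
must be ground truth, not a proxy), restricted to the narrow (41-56) or
wide (36-59) closed `caghigh` interval, with features: both CAG allele
lengths, encoded gender, parent AAO and family history. Rows with a
missing feature (for example, no affected parent, hence no parent AAO)
are dropped and counted; at the default configuration that is a small
minority.

`evaluate_registry_cv()` evaluates every registry model and two fixed
baselines — the original Langbehn coefficients and a Langbehn curve refit
on each training fold by Levenberg-Marquardt from the published starting
values — under one shared, seeded 10-fold partition, so the comparisons
are paired. The default registry holds linear regression, a linear
support-vector regressor, a random forest, kNN, a single-hidden-layer
perceptron and three gradient-boosted tree configurations (depth-6 and
depth-3 tree boosters and a DART booster), all with library-default
hyperparameters pinned in the registry code. `rank_models()` sorts by
mean R2 with MAE tiebreak. Fitting the refit inside folds keeps it
comparable to the learners; a whole-data refit is a one-line call to
`refit_langbehn()` when a final formula is wanted.

Degenerate inputs are defined, not fatal: a constant target makes R2
undefined (returned as `NaN` with a flag) while MAE/RMSE are still exact;
a model that fails to fit is recorded as failed and the rest of the
registry is unaffected; refit non-convergence is an error carrying the
optimiser diagnostics, never a silent fallback to the initial values.

## Driving capability

Visits map to at most five annual slots by
`round((days - baseline) / 365)` with half rounded away from zero (a pure
nearest rule needs a tie direction; away-from-zero keeps the first visit
in slot 0 and a 1.5-year gap in slot 2). When two visits collide on a
slot the later-dated one is kept (most recent information), tagged
`collapsed_collision`. Unoccupied slots are filled with the sentinel
(default -999, validated against observed values at build time and
against the [-1, 1] range after scaling).

The holdout split assigns whole participants, 80/20, within groups
sharing the same number of missing slots, so train and test match on
visit-count structure; groups smaller than two are pooled with the
nearest group. Feature scaling to [-1, 1] is fitted on training observed
slots only; test values outside the training range are preserved, not
clipped — clipping would silently hide covariate shift. Class weights
follow `w_c = n / (C * n_c)` over observed, non-imputed labels; missing
or imputed labels get sample weight 0, as does the next-year label at a
participant's final observed slot (it is unobservable, not guessable).

The classifier is a stack of GRU layers with a masking rule and two
sigmoid heads (current status, next-year status), trained with weighted
binary cross-entropy (heads weighted 1:1), an L2 penalty on kernel,
recurrent and head weights, and Adam at learning rate 1e-5. It is
implemented in compiled code (RcppArmadillo) with exact
backpropagation-through-time; the analytic gradients are verified against
central finite differences in the test suite at around 1e-10. Masked
slots are skipped *exactly*: the hidden state is carried through
unchanged and masked features and weight-0 labels enter no sum at all, so
perturbing them leaves losses, gradients, trained weights and predictions
bit-identical — an invariance the suite asserts literally. Output heads
start at zero so the earliest updates align them with informative hidden
directions instead of fighting a random readout.

Tuning crosses layers {3, 5}, hidden size {128, 256, 512} and L2 {1e-7,
1e-5, 1e-3} — 18 configurations — selecting by test AUC with F1 tiebreak
(the two criteria are combined as primary/tiebreak because they can
disagree). Epochs (250) and batch size (32) are convergence choices for
the cohort sizes the package targets, set so training approaches the
generator's separability ceiling within a few minutes per run on one
core; they are ordinary config fields. Headline metrics pool both heads'
weight-eligible slots (per-head values are always reported alongside);
pooling is a documented choice where the convention is ambiguous.

Calibration bands split predicted probabilities into ten equal bins
(closed top edge) and attach the empirical test accuracy of each bin, so
a personalised trajectory (`predict_trajectory()`) can annotate every
probability — including the appended one-step-ahead prediction — with how
reliable predictions of that confidence were on held-out data. Advice is
positive at probability >= threshold (boundary inclusive, documented).

## Problem sizes and reproducibility

The test-suite and acceptance-script experiments run at sizes chosen to
make their statistical claims stable on a single core in minutes:
structural recovery at 1,000 participants, the cascade comparison on
2,000 rows with 20% MCAR, the AAO benchmark at 2,500 participants, and
the driving experiment at 1,000 participants averaged over three
train/test seeds. Every stage is deterministic given its seed; the
pipeline derives per-stage seeds from one global seed through a stage-name
hash (`stage_seed()`), so any stage can be re-run in isolation
bit-identically. The one caveat is floating-point: results are exact for
a fixed BLAS; across BLAS builds tiny differences in linear algebra can
move CV scores in the last digits.

## Known limitations

* The cascade is single imputation; it propagates no uncertainty.
* Ranking-based model choice at 10 folds is noisy for weakly predictable
  variables; the report keeps all candidate scores so the margin is
  visible.
* The GRU uses fixed one-year slots; irregular-interval time encodings are
  out of scope.
* Synthetic results bound what the pipeline can do under its own
  generative assumptions; they say nothing about the access-controlled
  cohort's actual values.
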