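---
title: "Methods: multimodal decision-level fusion for injury-risk severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal decision-level fusion for injury-risk severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modelling problem

Athlete-monitoring programmes collect data at mismatched frequencies: daily
internal training load (session-RPE) and wellness questionnaires, weekly
urinalysis panels, and physical performance tests every four weeks. The
outcome of interest — a lower-extremity non-contact injury (LENCI) in the
coming week, graded by days of training missed — is rare and severely
imbalanced. `lencifusion` implements a decision-level fusion protocol for
this setting: each modality gets its own classifier operating at its natural
frequency, and only their class-probability outputs ("decision scores") are
combined by a second-stage model. Errors of one modality's model therefore do
not propagate through shared feature space, and modalities can be upgraded
independently — which is exactly how the final daily model is formed.

## Feature engineering

* **Session load.** `sRPE = duration [min] × RPE [0–10]`, in arbitrary units
  (AU). One session per day is assumed; daily load is the day's total.
* **Training monotony** (`TL-1`). Mean of the 7 trailing daily loads divided
  by their *population* standard deviation (divisor 7 inside the radical).
  The population form is deliberate: the week is the entire object of
  interest, not a sample from a longer exchangeable series. A zero-variance
  week makes TM undefined; the row is emitted with a missing value and a
  warning rather than an arbitrary number.
* **EWMA** (`TL-2`, `PW-2..6`). `y_t = λ x_t + (1 − λ) y_{t−1}`,
  `λ = 2/(N+1)`, `N = 7` days. The series is initialised at the first
  observation (`y_1 = x_1`): with 20-week series a burn-in convention changes
  almost nothing, and this choice avoids biasing the first anchored windows.
  Wellness items enter only as daily EWMAs — no trend features — because
  5-point Likert items move too coarsely day to day for trends to be
  meaningful.
* **Windows and labels.** Each anchor carries a complete 7-day trailing
  aggregation window and a 7-day leading prediction window. The label is the
  *maximum* severity of any LENCI inside the prediction window
  (risk-dominant labelling; bands: none = 0, 0–3 days missed = 1, 4–7 = 2,
  8–28 = 3, ≥ 29 = 4). The first and last season weeks are excluded, as the
  windows there are structurally incomplete.
* **Dataset A vs B.** A anchors weekly on the urinalysis day (the only named
  weekly collection point); B anchors daily. Weekly and 4-weekly panels are
  attached by last-observation-carried-forward per athlete, backfilled only
  before the first collection; urinalysis collected on menses days is
  discarded before imputation because the panel is not interpretable then.
  For dataset A the wellness/load summary is the last in-window EWMA value by
  default; a window-mean option exists (`wellness_aggregate = "mean"`) since
  the aggregation rule is a genuinely open choice.
* **Normalisation.** Per-athlete z-scores (population SD; a constant series
  maps to zeros with a warning) express every feature relative to the
  athlete's habitual level. The default normalises over each athlete's full
  series, which mirrors how per-athlete normalisation is usually described
  for this protocol but leaks a small amount of validation information into
  training folds; `cross_validate(normalize = "fold")` refits the
  normalisation inside each training fold for a leak-free variant. The
  leakage-guard tests cover the harness itself (SMOTE and fitting never see
  validation rows) independently of this choice.

## Class imbalance

Two mechanisms are used where the protocol uses them:

* **SMOTE** inside training folds only. A synthetic minority point is
  `d + u (d_n − d)`, `u ~ U(0,1)`, with `d_n` drawn from the `k = 5` nearest
  same-class neighbours (Euclidean distance). The interpolation *toward* the
  neighbour is the canonical rule and the default; the variant
  `direction = "as_printed"` (`d + u (d − d_n)`), which extrapolates away
  from the neighbour, is retained behind a flag because the protocol's
  printed formula carries that sign — almost certainly a typo, surfaced
  rather than hidden. Every synthetic row's provenance (base row, neighbour,
  `u`) is recorded, which is how the tests verify the defining identity
  against an independent k-NN computation. In small training folds `k` is
  capped at (minority size − 1) with a warning, and a singleton class falls
  back to duplication; `smote_oversample()` itself is strict.
* **Class weights** `n_sample / (n_class × N_c)` as per-sample weights in the
  fusion forest (and optionally in submodels). Balanced data gives unit
  weights; the weights conserve total mass.

## The fusion architecture

Submodels are XGBoost multi-class classifiers (`multi:softprob`), one per
modality block (PW 6 features, TL 2, PR 6, PP 4). Their decision scores are
the full class-probability vectors, concatenated in the fixed order PW, TL,
PR, PP (4 × 3 = 12 columns for the default 3-class space {0, 1, 2} — the
classes realised in practice; moderate/severe are supported by the label
coder but rarely materialise at these scales). The fusion layer is a
probability random forest (ranger) over the score columns with the class
weights above.

Two decisions where the protocol is underspecified:

* **Stacking leakage.** By default the fusion layer is trained on
  *out-of-fold* decision scores (5 internal stratified folds per submodel),
  so no score fed to the fusion forest was produced by a submodel that saw
  that row. `score_mode = "in_sample"` reproduces the naive reading. If an
  internal fold's training part collapses to a single class (possible in very
  small cohorts), that fold falls back to in-sample scores with a warning.
* **The daily substitution.** `build_dfusion()` retrains only the PW and TL
  submodels on dataset B and carries the PR and PP submodels *and the fusion
  layer* over unchanged — the closest reading of "replace the submodels to
  form the final model". `refit_fusion = TRUE` refits the forest on the daily
  scores instead. The substitution is logged in the model object.

Default hyperparameters (200 boosting rounds, depth 4, learning rate 0.1;
500 fusion trees) stand in for an unavailable tuning appendix; they are
exposed in `fusion_params()`, recorded in every saved model bundle, and are
not claimed to be optimal.

## Evaluation

Stratified k-fold cross-validation (default k = 10; per-class fold sizes
differ by at most one; `k` shrinks with a warning when a class is smaller
than `k`, or errors in strict mode). Metrics are one-vs-rest per label —
precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F2 `5PR/(4P+R)` (recall weighted
four-fold: a missed diagnosis costs more than a false alarm) — averaged with
weights equal to each label's support. An athlete-grouped CV mode exists
because row-level splits let athlete identity leak across folds; row-level
remains the default as it matches the protocol being reproduced.

Decision curve analysis binarises the 3-class model as positive = any
predicted injury risk with score `p_i = 1 − P(non-injured)` — the only
mapping consistent with a binary treat/don't-treat decision on top of a
severity model. Net benefits follow the standard treated / untreated /
treat-all algebra; the treat-all curve crosses zero exactly at prevalence,
which the tests assert as an identity. The default threshold grid is
0.01–0.99 in steps of 0.01.

Model comparisons on fold-level metrics use Welch's t-test (two models) or
Welch's ANOVA (`oneway.test`, unequal variances), with bands p < 0.01 highly
significant, < 0.05 significant, < 0.1 marginal. Degenerate (zero-variance)
comparisons are reported as undefined rather than silently dropped.

## Interpretation

Submodel feature weights use XGBoost's built-in TreeSHAP per class, and the
`mean|SHAP|` aggregation with relative weights (share of the total). For the
fusion layer no tree-path explainer is available in this stack, so the
package implements a Monte-Carlo sampling Shapley estimator (permutation
sampling with background-row imputation) over the 12 score columns, grouped
by originating submodel. SHAP slices are taken per class, and per-class
weights are evaluated on the rows truly in that class — attributions toward a
rare class computed on the majority rows are dominated by noise. Risk
networks connect features by the Spearman correlation of their per-sample
SHAP columns (default edge threshold |rho| ≥ 0.3 — no canonical value
exists, so it is a visible parameter), with node sizes from Welch t
statistics against the non-injured reference; the reference network's own
nodes sit at the standard size.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised: 16 athletes, 20 weeks, one session per day, daily load
~N(1083.5, 700²) AU truncated at zero (the 700 AU daily SD is chosen so the
*smoothed* load series has SD ≈ 265 AU and weekly monotony sits near 1.5,
matching the reference cohort's summaries), Likert wellness via truncated
normals rounded to 1–5, a fixed 28-day menses cycle with athlete-specific
phase, weekly urinalysis codes drawn from categorical distributions matched
to the reference marginals, and 4-weekly physical tests with slow drift.
Between-athlete variance components are not published anywhere, so they are
exposed as configuration with documented defaults (e.g. 80 AU between-athlete
load SD, 0.15 Likert points for wellness).

Injuries arise from a weekly multinomial logit over {none, minimal, mild}
whose linear predictor applies `hazard_coefficients` (log-odds per SD) to the
z-scored end-of-week feature state. Two calibration details matter:

* Intercepts are calibrated by quadrature so the *marginal* class
  frequencies match `target_class_ratio` (default 81:5:1) given the
  coefficient magnitudes; with all coefficients zero the calibration is
  exact. Supplying explicit intercepts bypasses this, which is what the
  hazard-monotonicity tests do.
* Slow-moving modalities are standardised on the *within-athlete* scale
  (physical tests are centred on each athlete's own expected trajectory and
  scaled by drift-plus-noise variation; training monotony's location/scale
  come from a fixed-seed internal simulation of the configured load model).
  Without this, a physical-performance hazard effect is a near-constant
  per-athlete frailty that the pipeline's per-athlete normalisation erases —
  the generated data would contain signal the features cannot express.

The generator does **not** model physiology mechanistically, kinematics,
inter-feature causal structure, seasonality of load prescription, menstrual
effects on wellness, or dropout/missingness beyond the designed collection
frequencies. Passing tests on this cohort therefore demonstrate that the
pipeline recovers structure *of the kind it assumes*, not that the model is
valid for any real squad.

Default hazard coefficients spread signal across all four modalities
(soreness and stress EWMAs, monotony and load EWMA, urine protein and
urobilinogen, squat 1RM negatively and the long shuttle positively), echoing
the qualitative pattern reported for the reference cohort.

## Test design and problem sizes

The suite runs entirely on generated data. Sizes were chosen to keep the
default run inside a normal desktop budget: the fusion-dominance property
uses 20 seeded cohorts at the default 16 × 20 conditions with 3-fold
cross-validated, fold-averaged weighted F2 (the fold average, not a single
split, is the protocol's own comparison unit); decision-curve dominance uses
10 seeds on the daily table; planted-signal recovery uses 20 seeds with
coefficients of ±1.5 log-odds per SD planted on one feature per modality
(PW-4, TL-2, PR-3, PP-1) and shallower boosters (60 rounds, depth 3) — the
magnitude and the choice of a *varying* urine feature (pH rather than the
82%-constant urobilinogen code) come from a power analysis: a planted-signal
test must plant a signal the feature representation can carry. Monte-Carlo
checks (dummy-classifier calibration, class-ratio fidelity) use 3-standard-
error bands around analytic expectations.

## Known limitations

* Sixteen athletes is a small cohort; row-level CV shares athletes across
  folds, and the global z-scoring default shares athlete-level statistics
  across folds. Both leak-free variants are provided but are not the
  reproduction defaults.
* The urinalysis specific-gravity coding in the reference tables is
  internally inconsistent (codes {1, 2} vs a reported mean of 2.4); the
  generator follows the code-set definition.
* Cross-validating `recipe_fusion()` retrains the full architecture per fold,
  which is the honest protocol but means small folds can degrade submodels
  (the out-of-fold machinery then falls back with warnings).
* The sampling Shapley estimator is stochastic; `nsim` trades accuracy for
  time and its Monte-Carlo error is visible in small `nsim` runs.
* No external validation is possible inside the package; all conclusions are
  conditional on the generator's assumptions.
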