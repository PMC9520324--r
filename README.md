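# lencifusion

Decision-level multimodal fusion models for predicting the severity of
**l**ower-**e**xtremity **n**on-**c**ontact **i**njury (LENCI) risk in
athletes from routine monitoring data.

Team-sport monitoring produces multi-source longitudinal data collected at
different frequencies: daily session-RPE training load and wellness
questionnaires, weekly urinalysis, and four-weekly physical performance
tests. `lencifusion` implements a modelling protocol for such data aimed at
sport scientists and team medical staff:

1. **Feature engineering.** Each athlete-day is summarised by sliding
   windows: session load `sRPE = duration × RPE`; weekly training monotony
   `TM = mean(load) / sd(load)` (population SD over the 7 trailing days);
   exponentially weighted moving averages
   `EWMA_t = λ x_t + (1 − λ) EWMA_{t−1}` with `λ = 2/(N+1)`, `N = 7`, for
   load and the five wellness items; and per-athlete z-scores
   `z = (x − μ_athlete)/σ_athlete`. The outcome of each exposure window is
   the worst LENCI severity in the *next* 7 days, banded by days of training
   missed (0–3 minimal, 4–7 mild, 8–28 moderate, ≥ 29 severe).
2. **Two dataset frequencies.** Dataset A anchors one row per athlete-week
   (on the weekly urinalysis day); dataset B anchors one row per athlete-day,
   with weekly/4-weekly panels carried forward per athlete (urinalysis
   collected during menses is discarded first).
3. **Fusion architecture.** One gradient-boosted (XGBoost) submodel per
   modality — perceived wellness (PW), training load (TL), physiological
   response (PR), physical performance (PP) — produces class-probability
   *decision scores*; a random forest fuses the concatenated scores, with
   per-sample class weights `n_sample / (n_class × N_c)` against the severe
   label imbalance (≈ 81:5:1). The weekly model (`wFusionModel`) is upgraded
   to the final `dFusionModel` by retraining the PW and TL submodels at daily
   frequency and substituting them in.
4. **Evaluation and interpretation.** Stratified 10-fold cross-validation
   with SMOTE applied only inside training folds; support-weighted precision,
   recall and F2 (`5PR/(4P+R)`); decision curve analysis with net benefit
   `TP/n − FP/n · p_t/(1 − p_t)`; Welch t / Welch ANOVA comparisons; SHAP
   feature weights `mean|SHAP|` and Spearman-correlation risk networks per
   severity class.

Because athlete-monitoring registries are rarely shareable, the package ships
a **seeded synthetic cohort generator** that emulates the collection
frequencies, marginal distributions and class imbalance of a 20-week,
16-athlete youth basketball squad, with a configurable multinomial-logit
injury hazard linking the feature state to next-week severity. Every stage of
the pipeline is testable end to end with no external data.

## Worked example

```r
library(lencifusion)

cfg    <- cohort_config(n_athletes = 8, n_weeks = 12)
cohort <- generate_cohort(cfg, seed = 42)
cohort
#> <monitoring_dataset>
#>   athletes: 8  days: 84
#>   daily: 672 rows | urine: 96 | physical: 24 | injuries: 9

table_a <- assemble_dataset(cohort, "A")   # weekly rows
table_b <- assemble_dataset(cohort, "B")   # daily rows
table_a
#> <modal_feature_table> frequency A, 80 rows, labels: 0=73 1=7

class_weights(table_a$label)
#>     0     1
#> 0.548 5.714

params  <- fusion_params(submodel_nrounds = 60, submodel_max_depth = 3,
                         fusion_num_trees = 300, oof_folds = 3, seed = 42)
wfusion <- build_wfusion(table_a, params)
dfusion <- build_dfusion(wfusion, table_b)
dfusion
#> <fusion_model> dFusionModel | classes: 0,1,2 | fusion: 300-tree RF
#>   PW submodel (B): 6 features, 60 rounds
#>   TL submodel (B): 2 features, 60 rounds
#>   PR submodel (A): 6 features, 60 rounds
#>   PP submodel (A): 4 features, 60 rounds
#>   substitutions: PW weekly->daily, TL weekly->daily

cv <- cross_validate(recipe_fusion(params), table_b, k = 3,
                     smote = smote_config(k = 3, seed = 42), seed = 42)
cv
#> <cv_report> FusionModel, 3 folds
#>   weighted precision 0.9200 +/- 0.0183
#>   weighted recall    0.9232 +/- 0.0191
#>   weighted f2        0.9223 +/- 0.0188
```

The cross-validated report says that on this small demo cohort the fusion
model recovers ~92% support-weighted precision and recall over the three
severity classes; the per-label breakdown sits in `cv$per_label` and the
pooled confusion matrix in `cv$confusion`. Downstream,
`dca_curve(dfusion, table_b)` returns the net-benefit curve
(`autoplot()`-able), `submodel_weights()` attributes the fusion decision to
its four submodels, `class_shap_matrices()` + `build_network()` build the
per-severity risk networks, and `integration_baselines()` runs the LR / SVM /
KNN / NB / DT / RF / XGBoost / dummy-classifier comparison through the
identical harness. `run_pipeline()` chains everything from a YAML config into
a directory of CSV/JSON/GraphML artefacts with a hashed run manifest (see
`inst/extdata/demo-config.yaml`).

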