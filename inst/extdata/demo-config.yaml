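# Demo pipeline configuration: a small squad so the full run finishes in
# minutes on one CPU. Field meanings mirror cohort_config(), fusion_params(),
# smote_config() and the evaluation/interpretation arguments.
seed: 1
cohort:
  n_athletes: 8
  n_weeks: 12
smote:
  k: 3
model:
  submodel_nrounds: 60
  submodel_max_depth: 3
  fusion_num_trees: 300
  oof_folds: 3
evaluation:
  k: 3
  frequency: A
  baselines: [DC, DT, RF]
interpretation:
  nsim: 8
  edge_threshold: 0.3
  max_rows: 150
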