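Package: lencifusion
Title: Multimodal Decision-Level Fusion Models for Lower-Extremity
    Non-Contact Injury Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates decision-level multimodal fusion models
    that predict the severity of lower-extremity non-contact injuries
    (LENCI) in athletes from routine monitoring data. Includes a seeded
    synthetic cohort generator emulating daily session-RPE training load,
    wellness questionnaires, weekly urinalysis and four-weekly physical
    tests; sliding-window feature engineering (EWMA, training monotony,
    per-athlete z-scores); SMOTE oversampling and class-weight handling for
    rare injury classes; gradient-boosted unimodal submodels fused by a
    class-weighted random forest; support-weighted multi-class evaluation
    under stratified cross-validation; decision curve analysis; and
    SHAP-based feature weighting with Welch tests and Spearman risk
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
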