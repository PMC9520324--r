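#' Reference tables from the motivating cohort study
#'
#' Published summary tables of the 20-week routine-monitoring study of sixteen
#' youth female basketball players whose protocol this package implements.
#' They serve as fixed inputs for benchmark arithmetic: per-site severity
#' counts of the 27 recorded lower-extremity non-contact injuries, and the
#' cross-validated weighted metrics of the data-integration baselines and the
#' daily fusion model.
#'
#' @return `lenci_site_severity_counts()`: tibble of injury counts by site and
#'   severity band. `integration_reference_metrics()`: tibble of weighted
#'   precision/recall/F2 (mean and SD over 10 folds) per model.
#' @export
lenci_site_severity_counts <- function() {
  tibble(
    site = c("hip", "knee", "thigh", "calf", "ankle", "foot"),
    minimal = c(0L, 2L, 5L, 10L, 0L, 5L),
    mild = c(0L, 2L, 0L, 0L, 0L, 2L),
    moderate = c(0L, 0L, 0L, 0L, 0L, 1L),
    severe = c(0L, 0L, 0L, 0L, 0L, 0L)
  )
}

#' @rdname lenci_site_severity_counts
#' @export
integration_reference_metrics <- function() {
  tibble(
    model = c("DC", "LR", "SVM", "KNN", "NB", "DT", "RF", "XGBoost",
              "dFusionModel"),
    precision = c(0.8670, 0.8906, 0.9206, 0.8961, 0.9007, 0.9026, 0.9169,
                  0.9141, 0.9881),
    precision_sd = c(0.0143, 0.0223, 0.0269, 0.0175, 0.0260, 0.0260, 0.0355,
                     0.0322, 0.0423),
    recall = c(0.3506, 0.5638, 0.9045, 0.8023, 0.6223, 0.8244, 0.9183,
               0.8813, 0.9912),
    recall_sd = c(0.0116, 0.1150, 0.0351, 0.0365, 0.1208, 0.1105, 0.0898,
                  0.0600, 0.0312),
    f2 = c(0.3857, 0.5916, 0.9050, 0.8140, 0.6422, 0.8324, 0.9152, 0.8835,
           0.9903),
    f2_sd = c(0.0089, 0.1048, 0.0330, 0.0322, 0.1163, 0.1003, 0.0833, 0.0348,
              0.0348)
  )
}

#' Injury-site shares and the high-severity share
#'
#' Recomputes, from a site-by-severity count table, each site's percentage
#' share of all lower-extremity non-contact injuries and the share of injuries
#' costing at least four days of training (mild or worse).
#'
#' @param counts A count table shaped like [lenci_site_severity_counts()].
#' @return List with `by_site` (tibble: site, count, share_pct) and
#'   `severe_share_pct` (percentage with >= 4 days missed).
#' @export
injury_site_shares <- function(counts = lenci_site_severity_counts()) {
  bands <- c("minimal", "mild", "moderate", "severe")
  counts$count <- rowSums(as.matrix(counts[, bands]))
  total <- sum(counts$count)
  by_site <- tibble(site = counts$site, count = counts$count,
                    share_pct = 100 * counts$count / total)
  severe <- sum(as.matrix(counts[, c("mild", "moderate", "severe")]))
  list(by_site = by_site, severe_share_pct = 100 * severe / total)
}

#' Improvement of the fusion model over the mean integration baseline
#'
#' Computes, from a benchmark metric table, the fusion model's weighted
#' precision and recall minus the mean over the seven integration baselines
#' (the dummy classifier is excluded), in percentage points.
#'
#' @param metrics A metric table shaped like
#'   [integration_reference_metrics()].
#' @param fusion Name of the fusion model row.
#' @param baselines Names of the baseline rows to average.
#' @return Tibble: `metric`, `fusion`, `baseline_mean`,
#'   `improvement_pct_points`.
#' @export
integration_improvement <- function(metrics = integration_reference_metrics(),
                                    fusion = "dFusionModel",
                                    baselines = c("LR", "SVM", "KNN", "NB",
                                                  "DT", "RF", "XGBoost")) {
  stopifnot(fusion %in% metrics$model, all(baselines %in% metrics$model))
  fu <- metrics[metrics$model == fusion, ]
  ba <- metrics[metrics$model %in% baselines, ]
  purrr::map_dfr(c("precision", "recall"), function(m) {
    tibble(metric = m, fusion = fu[[m]], baseline_mean = mean(ba[[m]]),
           improvement_pct_points = 100 * (fu[[m]] - mean(ba[[m]])))
  })
}
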