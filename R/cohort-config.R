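#' Configuration for a synthetic athlete-monitoring cohort
#'
#' Defines the study conditions the generator emulates: a squad monitored over
#' a season with daily session-RPE and wellness collection, weekly urinalysis
#' (Wednesdays), four-weekly physical testing, and a weekly multinomial-logit
#' injury hazard over the classes {non-injured, minimal, mild}. Defaults mirror
#' the marginal summaries and collection frequencies of the motivating cohort:
#' 16 athletes over 20 weeks, daily load with mean 1083.5 AU and SD 265 AU, and
#' a 81:5:1 outcome imbalance.
#'
#' @param n_athletes Number of athletes in the squad.
#' @param n_weeks Season length in weeks (>= 4, one full physical-test cycle).
#' @param sessions_per_week Training days per week (1-7); non-training days
#'   carry zero load but still produce a wellness record.
#' @param wellness_mean,wellness_sd Named per-item mean and marginal SD of the
#'   five Likert wellness items (fatigue, sleep, muscle_soreness, stress,
#'   desire) on the 1-5 scale.
#' @param wellness_between_sd Between-athlete SD of the wellness item means.
#' @param srpe_mean,srpe_sd Mean and marginal SD of *daily* session-RPE load
#'   (AU). The default SD of 700 AU is chosen so that the smoothed (EWMA)
#'   load series has SD near 265 AU and weekly training monotony sits near
#'   1.5, the summary values of the motivating cohort.
#' @param srpe_between_sd Between-athlete SD of habitual daily load (AU).
#' @param menses_cycle_days,menses_days Menstrual cycle length and duration of
#'   the flagged phase, in days; each athlete gets a random phase.
#' @param urine_category_probs Named list of probability vectors over the coded
#'   urinalysis categories (protein, urobilinogen, ph, specific_gravity, blood,
#'   ketones); each must sum to 1.
#' @param phys_test_mean,phys_test_sd Named mean and between-athlete SD of the
#'   four physical tests: squat_1rm (kg), shuttle_58 (s), shuttle_15 (s),
#'   mvj (cm).
#' @param phys_test_drift Per-cycle drift of each test (slow training effect).
#' @param phys_test_noise_sd Test-retest noise SD per test.
#' @param hazard_intercepts Log-odds intercepts of the minimal and mild injury
#'   classes versus non-injured, per athlete-week. When `NULL` (default) they
#'   are calibrated with [calibrate_hazard_intercepts()] so the *marginal*
#'   class frequencies match `target_class_ratio` given the hazard
#'   coefficients; supply explicit values to fix the hazard mechanism itself.
#' @param hazard_coefficients Named vector mapping feature encodings (e.g.
#'   `"TL-2"`) to log-odds per reference SD of that feature; applied to the
#'   z-scored current feature state in both injury classes' linear predictors.
#' @param target_class_ratio Three positive reals; the intended non-injured :
#'   minimal : mild frequency ratio.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(
    n_athletes = 16,
    n_weeks = 20,
    sessions_per_week = 7,
    wellness_mean = c(fatigue = 3.019, sleep = 3.094, muscle_soreness = 3.252,
                      stress = 3.044, desire = 2.988),
    wellness_sd = c(fatigue = 1.0, sleep = 1.1, muscle_soreness = 1.1,
                    stress = 1.3, desire = 0.5),
    wellness_between_sd = 0.15,
    srpe_mean = 1083.5,
    srpe_sd = 700,
    srpe_between_sd = 80,
    menses_cycle_days = 28,
    menses_days = 5,
    urine_category_probs = list(
      protein          = c(0.60, 0.20, 0.12, 0.06, 0.02),
      urobilinogen     = c(0.82, 0.12, 0.06),
      ph               = c(0.05, 0.30, 0.52, 0.13),
      specific_gravity = c(0.55, 0.45),
      blood            = c(0.60, 0.17, 0.10, 0.08, 0.05),
      ketones          = c(0.75, 0.17, 0.08)
    ),
    phys_test_mean = c(squat_1rm = 80.6, shuttle_58 = 9.75,
                       shuttle_15 = 67.6, mvj = 284.7),
    phys_test_sd = c(squat_1rm = 17.5, shuttle_58 = 0.60,
                     shuttle_15 = 1.95, mvj = 6.7),
    phys_test_drift = c(squat_1rm = 1.5, shuttle_58 = -0.05,
                        shuttle_15 = -0.30, mvj = 1.0),
    phys_test_noise_sd = c(squat_1rm = 2.0, shuttle_58 = 0.08,
                           shuttle_15 = 0.25, mvj = 1.0),
    hazard_intercepts = NULL,
    hazard_coefficients = c("PW-4" = 0.6, "PW-5" = 0.5, "TL-1" = 0.4,
                            "TL-2" = 0.7, "PR-1" = 0.5, "PR-2" = 0.4,
                            "PP-1" = -0.5, "PP-3" = 0.4),
    target_class_ratio = c(81, 5, 1),
    seed = NULL) {
  cfg <- list(
    n_athletes = n_athletes, n_weeks = n_weeks,
    sessions_per_week = sessions_per_week,
    wellness_mean = wellness_mean, wellness_sd = wellness_sd,
    wellness_between_sd = wellness_between_sd,
    srpe_mean = srpe_mean, srpe_sd = srpe_sd,
    srpe_between_sd = srpe_between_sd,
    menses_cycle_days = menses_cycle_days, menses_days = menses_days,
    urine_category_probs = urine_category_probs,
    phys_test_mean = phys_test_mean, phys_test_sd = phys_test_sd,
    phys_test_drift = phys_test_drift,
    phys_test_noise_sd = phys_test_noise_sd,
    hazard_intercepts = hazard_intercepts,
    hazard_coefficients = hazard_coefficients,
    target_class_ratio = target_class_ratio,
    seed = seed
  )
  calibrate <- is.null(cfg$hazard_intercepts)
  if (calibrate) cfg$hazard_intercepts <- c(minimal = 0, mild = 0)
  validate_cohort_config(cfg)
  if (calibrate) {
    cfg$hazard_intercepts <-
      log(c(minimal = target_class_ratio[2], mild = target_class_ratio[3]) /
            target_class_ratio[1])
    cfg <- calibrate_hazard_intercepts(cfg)
  }
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  bad <- function(field, msg) {
    abort(sprintf("Invalid cohort configuration: `%s` %s.", field, msg),
          class = "lenci_config_error")
  }
  if (cfg$n_weeks < 4) bad("n_weeks", "must be >= 4 (one physical-test cycle)")
  if (cfg$n_athletes < 1) bad("n_athletes", "must be >= 1")
  if (cfg$sessions_per_week < 1 || cfg$sessions_per_week > 7) {
    bad("sessions_per_week", "must lie in 1..7")
  }
  for (f in c("wellness_sd", "srpe_sd", "wellness_between_sd",
              "srpe_between_sd", "phys_test_sd", "phys_test_noise_sd")) {
    if (any(cfg[[f]] < 0)) bad(f, "must be non-negative")
  }
  items <- c("fatigue", "sleep", "muscle_soreness", "stress", "desire")
  if (!all(items %in% names(cfg$wellness_mean))) {
    bad("wellness_mean", "must name all five wellness items")
  }
  for (idx in names(URINE_CODES)) {
    p <- cfg$urine_category_probs[[idx]]
    if (is.null(p)) bad("urine_category_probs", paste0("is missing `", idx, "`"))
    if (length(p) != length(URINE_CODES[[idx]])) {
      bad("urine_category_probs", paste0("$", idx, " has the wrong length"))
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      bad("urine_category_probs", paste0("$", idx, " must sum to 1"))
    }
  }
  if (length(cfg$hazard_intercepts) != 2) {
    bad("hazard_intercepts", "must have one value per injury class (minimal, mild)")
  }
  if (length(cfg$hazard_coefficients) &&
      !all(names(cfg$hazard_coefficients) %in% FEATURE_NAMES)) {
    bad("hazard_coefficients", "must be named by feature encodings (PW-1..PP-4)")
  }
  if (length(cfg$target_class_ratio) != 3 || any(cfg$target_class_ratio <= 0)) {
    bad("target_class_ratio", "must be three positive values")
  }
  invisible(cfg)
}

#' Calibrate hazard intercepts to a target class ratio
#'
#' Solves for the multinomial-logit intercepts whose *marginal* class
#' probabilities match `target_class_ratio`, accounting for the spread that
#' nonzero hazard coefficients add to the linear predictor (both injury
#' classes share one coefficient vector, so the random part is a single
#' scalar `s * Z` with `s` the Euclidean norm of the coefficients and
#' `Z ~ N(0, 1)`). Uses deterministic quadrature plus fixed-point iteration.
#'
#' @param config A [cohort_config()].
#' @param tol Convergence tolerance on the marginal probabilities.
#' @return The config with recalibrated `hazard_intercepts`.
#' @export
calibrate_hazard_intercepts <- function(config, tol = 1e-10) {
  target <- config$target_class_ratio / sum(config$target_class_ratio)
  s <- sqrt(sum(config$hazard_coefficients^2))
  z <- seq(-8, 8, length.out = 4001)
  wq <- dnorm(z)
  wq <- wq / sum(wq)
  b <- config$hazard_intercepts
  marginal <- function(b) {
    e1 <- exp(b[1] + s * z)
    e2 <- exp(b[2] + s * z)
    den <- 1 + e1 + e2
    c(sum(wq * e1 / den), sum(wq * e2 / den))
  }
  for (i in 1:200) {
    p <- marginal(b)
    if (max(abs(p - target[2:3])) < tol) break
    b <- b + log(target[2:3]) - log(p)
  }
  config$hazard_intercepts <- b
  config
}
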