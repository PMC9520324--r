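#' Session rating of perceived exertion (sRPE)
#'
#' The internal training load of a session is the product of its duration in
#' minutes and the Borg CR-10 rating of perceived exertion, in arbitrary units
#' (AU). Daily load is the sum of the day's session loads.
#'
#' @param duration Session duration in minutes (>= 0). Vectorised.
#' @param rpe Rating of perceived exertion on the 0-10 scale. Vectorised.
#' @return Numeric vector of session loads (AU).
#' @examples
#' compute_srpe(60, 5)   # 300 AU
#' compute_srpe(90, 6.5) # 585 AU
#' @export
compute_srpe <- function(duration, rpe) {
  if (any(duration < 0, na.rm = TRUE)) {
    abort("`duration` must be non-negative.", class = "lenci_domain_error")
  }
  if (any(rpe < 0 | rpe > 10, na.rm = TRUE)) {
    abort("`rpe` must lie in [0, 10].", class = "lenci_domain_error")
  }
  duration * rpe
}

#' Exponentially weighted moving average
#'
#' Recursive EWMA with smoothing factor `2 / (N + 1)`, initialised at the first
#' observation: `out[1] = x[1]`, `out[t] = lambda * x[t] + (1 - lambda) *
#' out[t - 1]`.
#'
#' @param values Numeric series (non-empty, no missing values).
#' @param n Window-length parameter N; the smoothing factor is `2 / (n + 1)`.
#'   Defaults to 7, the aggregation-window length in days.
#' @return Numeric vector of the same length as `values`.
#' @examples
#' ewma_series(c(100, 200)) # 100, 125
#' @export
ewma_series <- function(values, n = 7) {
  if (length(values) == 0) {
    abort("`values` must be non-empty.", class = "lenci_domain_error")
  }
  if (n < 1) abort("`n` must be >= 1.", class = "lenci_domain_error")
  if (anyNA(values)) abort("`values` must not contain NA.", class = "lenci_domain_error")
  lambda <- 2 / (n + 1)
  out <- stats::filter(lambda * values, 1 - lambda,
                       method = "recursive", init = values[1])
  as.numeric(out)
}

#' Training monotony
#'
#' Weekly training monotony: the mean of seven consecutive daily loads divided
#' by their population standard deviation (divisor 7 inside the radical). High
#' values flag unvaried loading. Undefined (NA, with a warning) when the seven
#' loads are identical.
#'
#' @param loads Exactly seven daily training loads (AU).
#' @return A single number, or `NA` when the within-week SD is zero.
#' @examples
#' training_monotony(c(500, 600, 700, 800, 700, 600, 500))
#' @export
training_monotony <- function(loads) {
  if (length(loads) != 7) {
    abort("`loads` must contain exactly 7 daily values.",
          class = "lenci_domain_error")
  }
  s <- sd_pop(loads)
  if (s == 0) {
    warn("Training monotony undefined: zero within-week load variance.",
         class = "lenci_tm_undefined")
    return(NA_real_)
  }
  mean(loads) / s
}

#' Per-athlete z-score normalisation
#'
#' Standardises a series against its own mean and population standard
#' deviation, so that every athlete's features are expressed relative to that
#' athlete's habitual level. A constant series maps to all zeros with a
#' warning.
#'
#' @param values Numeric series with at least two observations.
#' @return Numeric vector with mean 0 and population SD 1 (when non-constant).
#' @examples
#' zscore(c(1, 2, 3))
#' @export
zscore <- function(values) {
  if (length(values) < 2) {
    abort("z-scoring needs at least 2 observations.",
          class = "lenci_domain_error")
  }
  s <- sd_pop(values)
  if (s == 0) {
    warn("Constant series: z-scores set to 0.", class = "lenci_zscore_constant")
    return(rep(0, length(values)))
  }
  (values - mean(values)) / s
}

#' Injury severity class from days of training missed
#'
#' Severity bands: no injury -> 0 (negative); 0-3 days missed -> 1 (minimal);
#' 4-7 -> 2 (mild); 8-28 -> 3 (moderate); >= 29 -> 4 (severe).
#'
#' @param days_missed Integer days of training missed, or `NA` for no injury.
#'   Vectorised.
#' @return Integer severity class in 0..4.
#' @examples
#' label_severity(c(NA, 0, 3, 4, 7, 8, 29))
#' @export
label_severity <- function(days_missed) {
  if (any(days_missed < 0, na.rm = TRUE)) {
    abort("`days_missed` must be non-negative.", class = "lenci_domain_error")
  }
  out <- rep(0L, length(days_missed))
  dm <- days_missed
  out[!is.na(dm) & dm <= 3] <- 1L
  out[!is.na(dm) & dm >= 4 & dm <= 7] <- 2L
  out[!is.na(dm) & dm >= 8 & dm <= 28] <- 3L
  out[!is.na(dm) & dm >= 29] <- 4L
  out
}
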