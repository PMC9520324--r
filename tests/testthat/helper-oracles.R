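# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the package implementation.

oracle_ewma <- function(x, n = 7) {
  lambda <- 2 / (n + 1)
  out <- numeric(length(x))
  out[1] <- x[1]
  if (length(x) > 1) {
    for (t in 2:length(x)) out[t] <- lambda * x[t] + (1 - lambda) * out[t - 1]
  }
  out
}

oracle_pop_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / length(x))
}

oracle_tm <- function(loads) {
  (sum(loads) / 7) / oracle_pop_sd(loads)
}

oracle_zscore <- function(x) {
  (x - mean(x)) / oracle_pop_sd(x)
}

oracle_class_weights <- function(labels) {
  classes <- sort(unique(labels))
  out <- vapply(classes, function(cl) {
    length(labels) / (length(classes) * sum(labels == cl))
  }, numeric(1))
  names(out) <- as.character(classes)
  out
}

oracle_weighted_metrics <- function(y_true, y_pred) {
  classes <- sort(unique(c(y_true, y_pred)))
  prec <- rec <- f2 <- supp <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[i] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[i] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f2[i] <- if (prec[i] == 0 && rec[i] == 0) 0 else
      5 * prec[i] * rec[i] / (4 * prec[i] + rec[i])
    supp[i] <- sum(y_true == cl)
  }
  list(precision = sum(supp * prec) / sum(supp),
       recall = sum(supp * rec) / sum(supp),
       f2 = sum(supp * f2) / sum(supp))
}

oracle_net_benefit <- function(y, p, pt) {
  n <- length(y)
  pos <- p >= pt
  tp <- sum(y == 1 & pos); fp <- sum(y == 0 & pos)
  tn <- sum(y == 0 & !pos); fn <- sum(y == 1 & !pos)
  c(treated = tp / n - fp / n * pt / (1 - pt),
    untreated = tn / n - fn / n * (1 - pt) / pt,
    treat_all = (tp + fn) / n - (tn + fp) / n * pt / (1 - pt))
}

# Welch's ANOVA (unequal-variance one-way F) from the textbook formulas.
oracle_welch_anova <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  w <- n / v
  mw <- sum(w * m) / sum(w)
  a <- sum(w * (m - mw)^2) / (k - 1)
  lam <- sum((1 - w / sum(w))^2 / (n - 1))
  b <- 1 + (2 * (k - 2) / (k^2 - 1)) * lam
  list(statistic = a / b, df1 = k - 1, df2 = (k^2 - 1) / (3 * lam))
}

# Spearman's rho from the rank formula (no ties assumed).
oracle_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A small toy feature table with all 18 encodings present; `signal` features
# carry the class signal, everything else is noise.
make_toy_table <- function(n = 120, signal = c("PW-2" = 2), classes = 0:1,
                           frequency = "A", seed = 1) {
  feats <- lencifusion:::FEATURE_NAMES
  withr::with_seed(seed, {
    label <- sample(classes, n, replace = TRUE)
    m <- matrix(rnorm(n * length(feats)), n,
                dimnames = list(NULL, feats))
    for (f in names(signal)) {
      m[, f] <- m[, f] + signal[[f]] * label
    }
    df <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
    df <- dplyr::bind_cols(
      tibble::tibble(athlete_id = sprintf("A%02d", sample(1:6, n, TRUE)),
                     anchor_date = as.Date("2021-01-01") + seq_len(n)),
      df)
    df$label <- as.integer(label)
    lencifusion:::new_modal_feature_table(df, frequency)
  })
}

# Hand-built four-table cohort for deterministic window/label checks.
make_fixture_cohort <- function(n_weeks = 5, injuries = NULL,
                                menses_days = integer(0),
                                urine_days = c(3, 10),
                                load = NULL) {
  n_days <- n_weeks * 7
  dates <- as.Date("2020-11-02") + seq_len(n_days) - 1
  if (is.null(load)) load <- 600 + 25 * ((seq_len(n_days) %% 7) + 1)
  daily <- tibble::tibble(
    athlete_id = "A01", date = dates,
    session_duration = load / 5, rpe = 5,
    fatigue = 3L, sleep = rep(c(2L, 3L, 4L), length.out = n_days),
    muscle_soreness = 3L, stress = rep(c(3L, 4L), length.out = n_days),
    desire = 3L,
    menses = as.integer(seq_len(n_days) %in% menses_days)
  )
  urine <- tibble::tibble(
    athlete_id = "A01", date = dates[urine_days],
    protein = 2, urobilinogen = 1, ph = 6, specific_gravity = 1,
    blood = 1, ketones = 1
  )
  physical <- tibble::tibble(
    athlete_id = "A01", date = dates[c(1, min(29, n_days))],
    squat_1rm = c(80, 85), shuttle_58 = c(9.8, 9.6),
    shuttle_15 = c(67, 66.5), mvj = c(284, 286)
  )
  inj <- if (is.null(injuries)) {
    tibble::tibble(athlete_id = character(), date = as.Date(character()),
                   site = character(), contact = integer(),
                   days_missed = integer())
  } else {
    injuries
  }
  lencifusion:::new_monitoring_dataset(daily, urine, physical, inj)
}

quiet_assemble <- function(...) {
  suppressWarnings(suppressMessages(assemble_dataset(...)))
}
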