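#' Group-wise z-scores
#'
#' Applies [zscore()] within each athlete's own series, the per-athlete
#' normalisation used before modelling.
#'
#' @param values Numeric vector.
#' @param athlete_id Grouping vector of the same length.
#' @return Numeric vector of within-athlete z-scores.
#' @export
zscore_per_athlete <- function(values, athlete_id) {
  if (length(values) != length(athlete_id)) {
    abort("`values` and `athlete_id` lengths differ.",
          class = "lenci_domain_error")
  }
  out <- numeric(length(values))
  for (g in split(seq_along(values), athlete_id)) {
    out[g] <- zscore(values[g])
  }
  out
}

# Rolling 7-day training monotony over a daily load series; NA for the first
# six days and for zero-variance weeks (flagged undefined).
rolling_tm <- function(load) {
  k <- rep(1 / 7, 7)
  m <- as.numeric(stats::filter(load, k, sides = 1))
  m2 <- as.numeric(stats::filter(load^2, k, sides = 1))
  s <- sqrt(pmax(m2 - m^2, 0))
  ifelse(is.na(m) | s < 1e-8, NA_real_, m / s)
}

# Daily per-athlete feature state (PW and TL blocks) plus next-window label.
daily_state <- function(dataset, pred_days = 7, ewma_n = 7) {
  items <- c("fatigue", "sleep", "muscle_soreness", "stress", "desire")
  inj <- dplyr::filter(dataset$injuries,
                       .data$contact == 0, .data$site %in% LE_SITES)
  inj$severity <- label_severity(inj$days_missed)

  one_athlete <- function(df) {
    df <- arrange(df, .data$date)
    load <- df$session_duration * df$rpe
    out <- tibble(
      athlete_id = df$athlete_id, date = df$date,
      `PW-1` = as.numeric(df$menses),
      `PW-2` = ewma_series(df$fatigue, ewma_n),
      `PW-3` = ewma_series(df$sleep, ewma_n),
      `PW-4` = ewma_series(df$muscle_soreness, ewma_n),
      `PW-5` = ewma_series(df$stress, ewma_n),
      `PW-6` = ewma_series(df$desire, ewma_n),
      `TL-1` = rolling_tm(load),
      `TL-2` = ewma_series(load, ewma_n)
    )
    ev <- inj[inj$athlete_id == df$athlete_id[1], ]
    out$label <- vapply(out$date, function(d) {
      hit <- ev$severity[ev$date > d & ev$date <= d + pred_days]
      if (length(hit)) max(hit) else 0L
    }, integer(1))
    out
  }
  dataset$daily |>
    dplyr::group_split(.data$athlete_id) |>
    purrr::map(one_athlete) |>
    bind_rows()
}

#' Windowed feature rows with next-window severity labels
#'
#' For every athlete and anchor date with a complete trailing aggregation
#' window, computes the training-load and wellness feature state (EWMA values
#' at the anchor, training monotony over the trailing week, menses flag on the
#' anchor day) and labels the row with the maximum severity of any
#' lower-extremity non-contact injury inside the leading prediction window.
#' Anchors in the first and last season weeks are excluded.
#'
#' @param dataset A `monitoring_dataset`.
#' @param agg_days Aggregation-window length in days (the trailing window; the
#'   training-monotony statistic is defined for 7).
#' @param pred_days Prediction-window length in days (the leading window).
#' @return Tibble of daily anchor rows: `athlete_id`, `anchor_date`, the
#'   `PW-*`/`TL-*` features and `label`, with a `skipped` attribute counting
#'   anchors dropped for incomplete windows.
#' @export
build_windows <- function(dataset, agg_days = 7, pred_days = 7) {
  if (agg_days != 7) {
    abort("`agg_days` must be 7: training monotony is a weekly statistic.",
          class = "lenci_config_error")
  }
  span <- as.integer(diff(range(dataset$daily$date))) + 1
  if (span < agg_days + pred_days) {
    abort("Dataset must span at least the aggregation plus prediction window.",
          class = "lenci_domain_error")
  }
  st <- daily_state(dataset, pred_days = pred_days)
  start <- min(dataset$daily$date)
  end <- max(dataset$daily$date)
  day_index <- as.integer(st$date - start) + 1
  week <- (day_index - 1) %/% 7 + 1
  n_weeks <- (as.integer(end - start) + 1) %/% 7
  keep <- day_index >= agg_days &
    as.integer(end - st$date) >= pred_days &
    week > 1 & week < n_weeks
  out <- st[keep, ]
  out <- rename(out, anchor_date = "date")
  attr(out, "skipped") <- sum(!keep)
  out
}

new_modal_feature_table <- function(df, frequency, normalization = NULL) {
  structure(df, class = c("modal_feature_table", class(df)),
            frequency = frequency, normalization = normalization)
}

#' Assemble a modality-partitioned feature table
#'
#' Builds the weekly table (frequency `"A"`, anchored on the weekly urinalysis
#' day) or the daily table (frequency `"B"`, one row per athlete-day) from a
#' monitoring cohort. Urinalysis panels collected on menses days are discarded
#' before imputation. Physiological (PR) and physical-performance (PP) values
#' are taken from the most recent collection at or before each anchor and
#' backfilled from the first collection before it; athletes with no PR or PP
#' collection at all are excluded with a message. Continuous features are then
#' z-scored per athlete.
#'
#' @param dataset A `monitoring_dataset`.
#' @param frequency `"A"` (weekly) or `"B"` (daily).
#' @param agg_days,pred_days Window lengths in days.
#' @param zscore Apply per-athlete z-scoring to the continuous features
#'   (everything except the binary menses flag). The fitted per-athlete mean
#'   and SD are stored in the `normalization` attribute.
#' @param wellness_aggregate For frequency `"A"`: take the `"last"` in-window
#'   EWMA value (default) or the `"mean"` of the window's daily EWMA values.
#' @return A `modal_feature_table` tibble: `athlete_id`, `anchor_date`, the 18
#'   feature encodings `PW-1..PP-4`, and `label`.
#' @export
assemble_dataset <- function(dataset, frequency = c("A", "B"),
                             agg_days = 7, pred_days = 7, zscore = TRUE,
                             wellness_aggregate = c("last", "mean")) {
  frequency <- match.arg(frequency)
  wellness_aggregate <- match.arg(wellness_aggregate)
  win <- build_windows(dataset, agg_days = agg_days, pred_days = pred_days)

  if (wellness_aggregate == "mean" && frequency == "A") {
    k <- rep(1 / agg_days, agg_days)
    win <- win |>
      group_by(.data$athlete_id) |>
      mutate(across(c("PW-2", "PW-3", "PW-4", "PW-5", "PW-6", "TL-2"),
                    ~ as.numeric(stats::filter(.x, k, sides = 1)))) |>
      ungroup()
  }

  if (frequency == "A") {
    wed <- format(win$anchor_date, "%u") == "3"
    win <- win[wed, ]
  }

  # Menses-day urinalysis is excluded before imputation.
  urine <- dataset$urine |>
    left_join(select(dataset$daily, "athlete_id", "date", "menses"),
              by = c("athlete_id", "date")) |>
    filter(is.na(.data$menses) | .data$menses == 0) |>
    select(-"menses")

  pr_cols <- names(URINE_CODES)
  pp_cols <- c("squat_1rm", "shuttle_58", "shuttle_15", "mvj")

  fill_block <- function(win, records, cols, out_names) {
    have <- unique(records$athlete_id)
    drop <- setdiff(unique(win$athlete_id), have)
    if (length(drop)) {
      inform(sprintf("Excluding athlete(s) with no %s collection: %s",
                     out_names[1], paste(drop, collapse = ", ")))
      win <- win[!win$athlete_id %in% drop, ]
    }
    blocks <- lapply(split(seq_len(nrow(win)), win$athlete_id), function(idx) {
      rec <- arrange(records[records$athlete_id == win$athlete_id[idx[1]], ],
                     .data$date)
      pos <- findInterval(win$anchor_date[idx], rec$date)
      pos[pos == 0] <- 1L  # backfill before the first collection
      as.matrix(rec[pos, cols])
    })
    m <- matrix(NA_real_, nrow(win), length(cols))
    for (g in names(blocks)) {
      m[win$athlete_id == g, ] <- blocks[[g]]
    }
    colnames(m) <- out_names
    bind_cols(win, as_tibble(m))
  }

  win <- fill_block(win, urine, pr_cols, paste0("PR-", 1:6))
  win <- fill_block(win, dataset$physical, pp_cols, paste0("PP-", 1:4))
  win <- select(win, "athlete_id", "anchor_date",
                dplyr::all_of(FEATURE_NAMES), "label")

  norm <- NULL
  if (zscore) {
    cont <- setdiff(FEATURE_NAMES, "PW-1")
    norm <- win |>
      tidyr::pivot_longer(dplyr::all_of(cont), names_to = "feature") |>
      group_by(.data$athlete_id, .data$feature) |>
      summarise(mu = mean(.data$value), sigma = sd_pop(.data$value),
                .groups = "drop")
    for (f in cont) {
      win[[f]] <- suppressWarnings(zscore_per_athlete(win[[f]], win$athlete_id))
    }
  }
  new_modal_feature_table(win, frequency, norm)
}

#' Extract the numeric feature matrix of a modality
#'
#' @param table A `modal_feature_table` (or any data frame with the feature
#'   encodings as columns).
#' @param modality One of `"PW"`, `"TL"`, `"PR"`, `"PP"`, or `NULL` for all
#'   four blocks concatenated.
#' @return Numeric matrix with feature encodings as column names.
#' @export
feature_matrix <- function(table, modality = NULL) {
  cols <- if (is.null(modality)) FEATURE_NAMES else MODALITIES[[modality]]
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    abort(sprintf("Missing feature column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "lenci_schema_error")
  }
  as.matrix(table[, cols])
}

#' @export
print.modal_feature_table <- function(x, ...) {
  cat(sprintf("<modal_feature_table> frequency %s, %d rows, labels: %s\n",
              attr(x, "frequency"), nrow(x),
              paste(sprintf("%d=%d", sort(unique(x$label)),
                            as.integer(table(x$label))), collapse = " ")))
  NextMethod()
}
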