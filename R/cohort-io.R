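#' Write / read a monitoring cohort as delimited text
#'
#' A cohort is stored as four UTF-8 CSV files with ISO-8601 dates:
#' `daily.csv`, `urine.csv`, `physical.csv`, `injuries.csv`. Reading validates
#' every invariant (Likert range, RPE range, urinalysis code sets, one daily
#' record per athlete-date) and reports the offending file and row.
#'
#' @param dataset A `monitoring_dataset`.
#' @param directory Target directory (created if absent).
#' @return `write_cohort()` returns the written file paths invisibly;
#'   `read_cohort()` returns a `monitoring_dataset`.
#' @export
write_cohort <- function(dataset, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- file.path(directory,
                     c("daily.csv", "urine.csv", "physical.csv", "injuries.csv"))
  readr::write_csv(dataset$daily, paths[1])
  readr::write_csv(dataset$urine, paths[2])
  readr::write_csv(dataset$physical, paths[3])
  readr::write_csv(dataset$injuries, paths[4])
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  need <- c("daily.csv", "urine.csv", "physical.csv", "injuries.csv")
  paths <- file.path(directory, need)
  missing <- need[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("Missing cohort file(s): %s", paste(missing, collapse = ", ")),
          class = "lenci_io_error")
  }
  rd <- function(p, types) {
    out <- tryCatch(
      readr::read_csv(p, col_types = types, progress = FALSE),
      error = function(e) abort(sprintf("Malformed file %s: %s", p,
                                        conditionMessage(e)),
                                class = "lenci_io_error")
    )
    prob <- readr::problems(out)
    if (nrow(prob) > 0) {
      abort(sprintf("Malformed file %s at line %d: %s", p, prob$row[1],
                    prob$expected[1]),
            class = "lenci_io_error")
    }
    out
  }
  daily <- rd(paths[1], "cDdddddddi")
  urine <- rd(paths[2], "cDdddddd")
  physical <- rd(paths[3], "cDdddd")
  injuries <- rd(paths[4], "cDcii")
  daily <- mutate(daily, across(c("fatigue", "sleep", "muscle_soreness",
                                  "stress", "desire"), as.integer))

  check_rows <- function(ok, file, what) {
    if (!all(ok)) {
      abort(sprintf("%s: %s at row %d", file, what, which(!ok)[1]),
            class = "lenci_io_error")
    }
  }
  for (item in c("fatigue", "sleep", "muscle_soreness", "stress", "desire")) {
    check_rows(daily[[item]] %in% 1:5, "daily.csv",
               sprintf("out-of-range Likert value in `%s`", item))
  }
  check_rows(daily$rpe >= 0 & daily$rpe <= 10, "daily.csv",
             "RPE outside [0, 10]")
  check_rows(daily$session_duration >= 0, "daily.csv", "negative duration")
  check_rows(daily$menses %in% 0:1, "daily.csv", "menses flag not 0/1")
  check_rows(!duplicated(daily[c("athlete_id", "date")]), "daily.csv",
             "duplicate athlete-date record")
  for (idx in names(URINE_CODES)) {
    check_rows(urine[[idx]] %in% URINE_CODES[[idx]], "urine.csv",
               sprintf("code outside the admissible set in `%s`", idx))
  }
  if (nrow(injuries)) {
    check_rows(injuries$site %in% LE_SITES, "injuries.csv", "unknown site")
    check_rows(injuries$days_missed >= 0, "injuries.csv",
               "negative days_missed")
    check_rows(injuries$contact %in% 0:1, "injuries.csv",
               "contact flag not 0/1")
  }
  horizon <- range(daily$date)
  check_rows(urine$date >= horizon[1] & urine$date <= horizon[2],
             "urine.csv", "date outside the study horizon")

  new_monitoring_dataset(daily, urine, physical, injuries)
}
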