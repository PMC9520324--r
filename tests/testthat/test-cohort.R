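small_cfg <- function(...) {
  cohort_config(n_athletes = 4, n_weeks = 8, ...)
}

test_that("the generator is deterministic given config and seed", {
  a <- generate_cohort(small_cfg(), seed = 5)
  b <- generate_cohort(small_cfg(), seed = 5)
  for (tb in c("daily", "urine", "physical", "injuries")) {
    expect_identical(a[[tb]], b[[tb]])
  }
  c <- generate_cohort(small_cfg(), seed = 6)
  expect_false(identical(a$daily, c$daily))
})

test_that("one physical-test record per athlete per 4-week cycle", {
  co <- generate_cohort(cohort_config(n_athletes = 1, n_weeks = 4), seed = 1)
  expect_identical(nrow(co$physical), 1L)
  co2 <- generate_cohort(cohort_config(n_athletes = 3, n_weeks = 9), seed = 1)
  expect_identical(nrow(co2$physical), 3L * 3L)
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(cohort_config(n_weeks = 3), "n_weeks",
               class = "lenci_config_error")
  expect_error(cohort_config(srpe_sd = -1), "srpe_sd",
               class = "lenci_config_error")
  expect_error(
    cohort_config(urine_category_probs = utils::modifyList(
      formals(cohort_config)$urine_category_probs |> eval(),
      list(ketones = c(0.5, 0.4, 0.2)))),
    "urine_category_probs", class = "lenci_config_error")
  expect_error(cohort_config(target_class_ratio = c(81, 5)),
               "target_class_ratio", class = "lenci_config_error")
  expect_error(generate_cohort(small_cfg()), class = "lenci_config_error")
})

test_that("with zero hazard coefficients the injury multinomial hits the target ratio", {
  cfg <- cohort_config(n_athletes = 20, n_weeks = 20,
                       hazard_coefficients = numeric(0))
  counts <- c(minimal = 0, mild = 0)
  weeks <- 0
  for (s in 1:15) {
    co <- generate_cohort(cfg, seed = s)
    sev <- label_severity(co$injuries$days_missed)
    counts["minimal"] <- counts["minimal"] + sum(sev == 1)
    counts["mild"] <- counts["mild"] + sum(sev == 2)
    weeks <- weeks + cfg$n_athletes * (cfg$n_weeks - 1)
  }
  target <- c(minimal = 5, mild = 1) / 87
  got <- counts / weeks
  expect_true(all(abs(got - target) / target < 0.3))
})

test_that("increasing a positive hazard coefficient increases the injury rate", {
  base_int <- log(c(minimal = 5, mild = 1) / 81)
  n_low <- n_high <- 0
  for (s in 1:20) {
    lo <- generate_cohort(
      cohort_config(n_athletes = 8, n_weeks = 10,
                    hazard_intercepts = base_int,
                    hazard_coefficients = c("TL-2" = 0.2)), seed = s)
    hi <- generate_cohort(
      cohort_config(n_athletes = 8, n_weeks = 10,
                    hazard_intercepts = base_int,
                    hazard_coefficients = c("TL-2" = 1.6)), seed = s)
    n_low <- n_low + nrow(lo$injuries)
    n_high <- n_high + nrow(hi$injuries)
  }
  expect_gt(n_high, n_low)
})

test_that("generated marginals track the configured means", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 3)
  b <- quiet_assemble(co, "B", zscore = FALSE)
  # between-athlete standard error of the athlete-level means
  se_of <- function(v, id) {
    m <- tapply(v, id, mean)
    stats::sd(m) / sqrt(length(m))
  }
  expect_lt(abs(mean(b$`TL-2`) - cfg$srpe_mean),
            3 * se_of(b$`TL-2`, b$athlete_id) + 0.02 * cfg$srpe_mean)
  expect_lt(abs(mean(b$`PW-2`) - cfg$wellness_mean[["fatigue"]]),
            3 * se_of(b$`PW-2`, b$athlete_id) + 0.05)
  expect_lt(abs(mean(b$`PW-1`) - cfg$menses_days / cfg$menses_cycle_days),
            3 * se_of(b$`PW-1`, b$athlete_id) + 0.02)
})

test_that("cohorts round-trip through delimited text exactly", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_cfg(), seed = 9)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  for (tb in c("daily", "urine", "physical", "injuries")) {
    expect_equal(as.data.frame(back[[tb]]), as.data.frame(co[[tb]]))
  }
})

test_that("malformed cohort files are rejected with the offending row", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_cfg(), seed = 9)
  write_cohort(co, dir)
  daily <- readr::read_csv(file.path(dir, "daily.csv"),
                           show_col_types = FALSE)
  daily$fatigue[13] <- 9
  readr::write_csv(daily, file.path(dir, "daily.csv"))
  expect_error(read_cohort(dir), "row 13", class = "lenci_io_error")
  expect_error(read_cohort(withr::local_tempdir()), "daily.csv",
               class = "lenci_io_error")
})

test_that("an injury-free cohort is valid and yields all-negative labels", {
  cfg <- small_cfg(hazard_intercepts = c(minimal = -30, mild = -30))
  co <- generate_cohort(cfg, seed = 2)
  expect_identical(nrow(co$injuries), 0L)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_identical(nrow(back$injuries), 0L)
  a <- quiet_assemble(back, "A")
  expect_true(all(a$label == 0L))
})
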