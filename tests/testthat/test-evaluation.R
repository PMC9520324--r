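test_that("the F2-score weighs recall four times precision", {
  expect_equal(f_beta(0.9, 0.9), 0.9, tolerance = 1e-12)
  expect_identical(f_beta(1, 0), 0)
  expect_equal(f_beta(0.5, 1.0), 5 * 0.5 / 3, tolerance = 1e-10)
  expect_equal(f_beta(0.5, 1.0), 0.83333, tolerance = 1e-5)
  expect_identical(f_beta(0, 0), 0)
  expect_error(f_beta(1.2, 0.5), class = "lenci_domain_error")
})

test_that("support-weighted metrics match the hand-weighted oracle", {
  # perfect predictions
  rep0 <- weighted_metrics(c(0, 1, 2, 0), c(0, 1, 2, 0))
  expect_equal(rep0$weighted$precision, 1)
  expect_equal(rep0$weighted$recall, 1)
  expect_equal(rep0$weighted$f2, 1)

  # supports {8, 1, 1}, per-label precision {1, 0.5, 1} -> weighted 0.95
  y_true <- c(rep(0, 8), 1, 2)
  y_pred <- c(rep(0, 7), 1, 1, 2)
  rep1 <- weighted_metrics(y_true, y_pred)
  expect_equal(rep1$per_label$precision, c(1, 0.5, 1))
  expect_equal(rep1$weighted$precision, 0.95, tolerance = 1e-12)

  # single-class truth: the weighted metric is that class's metric
  rep2 <- suppressMessages(weighted_metrics(rep(0, 6), c(0, 0, 0, 0, 0, 1)))
  expect_equal(rep2$weighted$recall,
               rep2$per_label$recall[rep2$per_label$label == 0])
  expect_message(weighted_metrics(rep(0, 3), c(0, 0, 5)), "zero support")

  # confusion-matrix bookkeeping
  expect_identical(sum(rep1$confusion), 10L)
  expect_identical(as.integer(diag(rep1$confusion)), c(7L, 1L, 1L))

  # oracle equivalence on random instances
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(5:60, 1)
      yt <- sample(0:2, n, replace = TRUE)
      yp <- sample(0:2, n, replace = TRUE)
      got <- suppressMessages(weighted_metrics(yt, yp))$weighted
      want <- oracle_weighted_metrics(yt, yp)
      expect_equal(got$precision, want$precision, tolerance = 1e-10)
      expect_equal(got$recall, want$recall, tolerance = 1e-10)
      expect_equal(got$f2, want$f2, tolerance = 1e-10)
      # weighted-average identity
      pl <- suppressMessages(weighted_metrics(yt, yp))$per_label
      expect_equal(sum(pl$support * pl$recall) / sum(pl$support),
                   got$recall, tolerance = 1e-12)
    }
  })
})

test_that("stratified folds balance classes to within one row", {
  tab <- make_toy_table(n = 130, classes = 0:2, seed = 12)
  withr::with_seed(1, fold <- lencifusion:::stratified_folds(tab$label, 5))
  for (cl in 0:2) {
    sizes <- table(fold[tab$label == cl])
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("k is reduced (or errors in strict mode) for tiny classes", {
  tab <- make_toy_table(n = 60, classes = 0:1, seed = 13)
  tab$label[1:3] <- 2L
  rec <- recipe_baseline("DT")
  expect_warning(cv <- cross_validate(rec, tab, k = 10, smote = NULL, seed = 1),
                 class = "lenci_k_reduced")
  expect_identical(cv$k, 3L)
  expect_error(cross_validate(rec, tab, k = 10, smote = NULL, strict = TRUE),
               class = "lenci_config_error")
})

test_that("the dummy classifier is calibrated: weighted recall ~ sum of squared priors", {
  withr::with_seed(17, {
    n <- 2000
    label <- sample(0:2, n, replace = TRUE, prob = c(0.9, 0.07, 0.03))
    tab <- make_toy_table(n = n, signal = c(), classes = 0:2, seed = 18)
    tab$label <- as.integer(label)
  })
  cv <- cross_validate(recipe_baseline("DC"), tab, k = 10, smote = NULL,
                       seed = 4)
  expected <- sum(c(0.9, 0.07, 0.03)^2)
  se <- sd(cv$folds$recall) / sqrt(nrow(cv$folds))
  expect_lt(abs(mean(cv$folds$recall) - expected), 3 * se + 0.01)
})

test_that("net benefit reproduces the defining arithmetic", {
  # TP = 10, FP = 5, n = 100 at p_t = 0.2
  y <- c(rep(1, 10), rep(0, 5), rep(0, 85))
  p <- c(rep(0.9, 15), rep(0.05, 85))
  nb <- net_benefit(y, p, 0.2)
  expect_equal(nb$treated, 0.0875, tolerance = 1e-12)
  # treat-all crosses zero exactly at prevalence
  prev <- mean(y)
  expect_equal(net_benefit(y, p, prev)$treat_all, 0, tolerance = 1e-12)
  # perfect classifier: treated = prevalence at any threshold
  expect_equal(net_benefit(y, y, 0.7)$treated, prev, tolerance = 1e-12)
  expect_error(net_benefit(y, p, 1), class = "lenci_domain_error")
  # brute-force oracle on random instances
  withr::with_seed(41, {
    for (i in 1:100) {
      n <- sample(20:200, 1)
      yy <- stats::rbinom(n, 1, 0.3)
      pp <- runif(n)
      pt <- runif(1, 0.02, 0.98)
      got <- net_benefit(yy, pp, pt)
      want <- oracle_net_benefit(yy, pp, pt)
      expect_equal(c(got$treated, got$untreated, got$treat_all),
                   unname(want), tolerance = 1e-10)
    }
  })
})

test_that("the treat-all curve is monotone and the low-threshold limit holds", {
  withr::with_seed(43, {
    y <- stats::rbinom(300, 1, 0.25)
    p <- pmin(pmax(0.25 + 0.4 * (y - 0.25) + rnorm(300, 0, 0.15), 0), 1)
  })
  grid <- seq(0.01, 0.99, 0.01)
  curve <- net_benefit_curve(y, p, grid)
  expect_true(all(diff(curve$treat_all) <= 1e-12))
  expect_equal(curve$treated[1], net_benefit(y, p, 0.01)$treated)
  # at p_t -> 0+ every row is treated: net benefit -> prevalence
  expect_equal(net_benefit(y, rep(1, length(y)), 1e-6)$treated, mean(y),
               tolerance = 1e-5)
})

test_that("Welch comparisons match textbook formulas", {
  res <- compare_models(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # degenerate variance is reported as undefined
  res0 <- compare_models(c(2, 2, 2), c(2, 2, 2))
  expect_identical(res0$band, "undefined")
  # Welch ANOVA against the independent textbook oracle
  withr::with_seed(53, {
    g <- list(rnorm(8, 0, 1), rnorm(12, 0.8, 2), rnorm(6, -0.5, 0.5))
  })
  res3 <- compare_models(g[[1]], g[[2]], g[[3]])
  want <- oracle_welch_anova(g)
  expect_equal(res3$statistic, want$statistic, tolerance = 1e-10)
  expect_identical(res3$test, "Welch ANOVA")
  # two-group Welch ANOVA F equals squared Welch t
  t2 <- compare_models(g[[1]], g[[2]])$statistic^2
  fa <- oneway.test(v ~ gr, data.frame(v = c(g[[1]], g[[2]]),
                                       gr = rep(1:2, c(8, 12))),
                    var.equal = FALSE)$statistic
  expect_equal(t2, unname(fa), tolerance = 1e-10)
})

test_that("every baseline runs through the same harness with one report schema", {
  tab <- make_toy_table(n = 90, signal = c("PW-2" = 3), classes = 0:1,
                        seed = 19)
  bl <- suppressWarnings(
    integration_baselines(tab, classifiers = c("DC", "LR", "DT", "KNN"),
                          k = 3, smote = smote_config(k = 3), seed = 2))
  expect_identical(bl$model, c("DC", "LR", "DT", "KNN"))
  expect_identical(names(bl), c("model", "precision", "precision_sd",
                                "recall", "recall_sd", "f2", "f2_sd"))
  reports <- attr(bl, "reports")
  expect_true(all(vapply(reports, function(r)
    identical(names(r$folds), c("fold", "precision", "recall", "f2")),
    logical(1))))
  expect_error(recipe_baseline("nope"), class = "lenci_config_error")
})
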