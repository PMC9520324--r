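test_that("mean absolute SHAP weights aggregate and normalise correctly", {
  m <- matrix(c(1, -3, -1, 1), 2, dimnames = list(NULL, c("a", "b")))
  w <- mean_abs_shap(m)
  expect_equal(w$mean_abs_shap, c(2, 1))
  expect_equal(w$relative_weight, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(w$relative_weight), 1, tolerance = 1e-12)
  # an all-zero column gets zero relative weight
  m2 <- cbind(m, z = c(0, 0))
  expect_equal(mean_abs_shap(m2)$relative_weight[3], 0)
  expect_error(mean_abs_shap(matrix(numeric(0), 0, 0)),
               class = "lenci_domain_error")
})

test_that("sampling Shapley recovers exact attributions of a linear model", {
  withr::with_seed(61, {
    n <- 60; p <- 4
    x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
    w <- c(2, -1, 0.5, 0)
    f <- function(m) cbind(lin = as.numeric(m %*% w))
    phi <- sampling_shap(f, x, nsim = 400, seed = 3)
    # for a linear model the Shapley value is w_j * (x_j - mean(x_j))
    want <- sweep(x, 2, colMeans(x)) %*% diag(w)
    expect_lt(max(abs(phi[, , 1] - want)), 0.6)
    # efficiency: contributions sum to f(x) - E[f(background)]
    expect_lt(max(abs(rowSums(phi[, , 1]) -
                        (f(x)[, 1] - mean(f(x)[, 1])))), 0.8)
  })
})

test_that("TreeSHAP submodel attributions flag the planted feature", {
  tab <- make_toy_table(n = 250, signal = c("PW-4" = 3), classes = 0:1,
                        seed = 21)
  sub <- train_submodel(tab, "PW", fusion_params(submodel_nrounds = 60,
                                                 seed = 1), classes = 0:1)
  sh <- submodel_shap(sub, tab)
  expect_identical(names(sh), c("0", "1"))
  w <- mean_abs_shap(sh[["1"]])
  expect_identical(w$feature[which.max(w$mean_abs_shap)], "PW-4")
})

test_that("submodel weights are normalised per class and find planted signal", {
  tab <- make_toy_table(n = 220, signal = c("PW-2" = 3, "PW-4" = 3),
                        classes = 0:1, seed = 22)
  model <- build_wfusion(tab, fusion_params(submodel_nrounds = 40,
                                            fusion_num_trees = 150,
                                            oof_folds = 3, seed = 5),
                         classes = 0:1)
  sw <- submodel_weights(model, tab[1:120, ], nsim = 15, seed = 2)
  sums <- as.numeric(tapply(sw$relative_weight, sw$class, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
  w1 <- sw[sw$class == 1, ]
  expect_identical(w1$submodel[which.max(w1$relative_weight)], "PW")
  ps <- attr(sw, "per_sample")
  expect_identical(dim(ps[["1"]]), c(120L, 4L))
  expect_error(submodel_weights(list(), tab), class = "lenci_state_error")
})

test_that("Welch weight tests behave under null, power and the F = t^2 identity", {
  same <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("i1", "i2")))
  res <- weight_difference_tests(list("0" = same, "1" = same))
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p_value == 1))
  # power: a 3-sigma shift at n = 30 is detected nearly always
  hits <- 0
  for (s in 1:40) {
    withr::with_seed(s, {
      a <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "i"))
      b <- matrix(rnorm(30, 3), 30, 1, dimnames = list(NULL, "i"))
    })
    p <- weight_difference_tests(list("0" = a, "1" = b))$p_value
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / 40, 0.95)
  # two groups: Welch ANOVA F equals the squared Welch t
  withr::with_seed(71, {
    a <- matrix(rnorm(12), 12, 1, dimnames = list(NULL, "i"))
    b <- matrix(rnorm(15, 1, 2), 15, 1, dimnames = list(NULL, "i"))
  })
  tt <- compare_models(a[, 1], b[, 1])
  ff <- oneway.test(v ~ g, data.frame(v = c(a[, 1], b[, 1]),
                                      g = rep(1:2, c(12, 15))),
                    var.equal = FALSE)
  expect_equal(tt$statistic^2, unname(ff$statistic), tolerance = 1e-10)
})

test_that("risk networks use rank correlations and Welch node statistics", {
  expect_equal(oracle_spearman(c(1, 2, 3), c(3, 1, 2)), -0.5)
  expect_equal(cor(c(1, 2, 3), c(3, 1, 2), method = "spearman"), -0.5)
  withr::with_seed(81, {
    n <- 40
    feats <- lencifusion:::FEATURE_NAMES
    base <- matrix(rnorm(n * 18), n, dimnames = list(NULL, feats))
    base[, "TL-2"] <- base[, "TL-1"]^3          # monotone coupling: rho = 1
    shifted <- base
    shifted[, "PW-2"] <- shifted[, "PW-2"] + 2  # bigger node in the target
  })
  net <- build_network(list("0" = base, "1" = shifted), "1")
  e <- net$edges[net$edges$from == "TL-1" & net$edges$to == "TL-2", ]
  expect_equal(e$rho, 1, tolerance = 1e-12)
  expect_true(all(abs(net$edges$rho) <= 1))
  expect_true(all(abs(net$edges$rho) >= 0.3))
  expect_gt(net$nodes$statistic[net$nodes$feature == "PW-2"], 2)
  expect_gt(net$nodes$size[net$nodes$feature == "PW-2"], 1)
  # the reference class against itself: all nodes at the standard size
  net0 <- build_network(list("0" = base, "1" = shifted), "0")
  expect_true(all(net0$nodes$statistic == 0))
  expect_true(all(net0$nodes$size == 1))
  # Spearman is invariant to monotone transforms
  m2 <- base; m2[, "TL-1"] <- exp(m2[, "TL-1"])
  net2 <- build_network(list("0" = m2, "1" = m2), "0")
  e2 <- net2$edges[net2$edges$from == "TL-1" & net2$edges$to == "TL-2", ]
  expect_equal(e2$rho, 1, tolerance = 1e-12)
  expect_error(build_network(list("0" = base[1:2, ], "1" = base[1:2, ]), "1"),
               class = "lenci_domain_error")
  # graph export round-trips node and edge counts
  g <- as_igraph(net)
  expect_equal(igraph::vcount(g), 18)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  expect_true(file.size(path) > 0)
})
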