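toy_params <- fusion_params(submodel_nrounds = 40, fusion_num_trees = 150,
                            oof_folds = 3, seed = 2)

test_that("a separable toy problem is learned perfectly and deterministically", {
  tab <- make_toy_table(n = 150, signal = c("PW-2" = 6), classes = 0:1)
  sub <- train_submodel(tab, "PW", toy_params, classes = 0:1)
  sc <- decision_scores(sub, tab)
  expect_identical(ncol(sc), 2L)
  pred <- c(0, 1)[max.col(sc, ties.method = "first")]
  expect_identical(pred, as.numeric(tab$label))
  # determinism
  sub2 <- train_submodel(tab, "PW", toy_params, classes = 0:1)
  expect_identical(decision_scores(sub2, tab), sc)
  # probability simplex and pointwise mapping
  expect_true(all(sc >= 0))
  expect_equal(rowSums(sc), rep(1, nrow(sc)), tolerance = 1e-7)
  dup <- tab[c(1, 1, 5), ]
  sdup <- decision_scores(sub, dup)
  expect_identical(sdup[1, ], sdup[2, ])
})

test_that("label permutation destroys out-of-sample skill", {
  tab <- make_toy_table(n = 200, signal = c("PW-2" = 6), classes = 0:1,
                        seed = 3)
  withr::with_seed(9, tab$label <- sample(tab$label))
  train <- tab[1:120, ]; test <- tab[121:200, ]
  sub <- train_submodel(train, "PW", toy_params, classes = 0:1)
  pred <- c(0, 1)[max.col(decision_scores(sub, test))]
  acc <- mean(pred == test$label)
  prior <- max(table(train$label)) / nrow(train)
  expect_lt(acc, prior + 0.15)
})

test_that("submodels refuse single-class training labels and missing features", {
  tab <- make_toy_table(n = 40, classes = 0:1)
  tab$label <- 0L
  expect_error(train_submodel(tab, "PW", toy_params),
               class = "lenci_training_error")
  tab2 <- make_toy_table(n = 40, classes = 0:1)
  sub <- train_submodel(tab2, "PW", toy_params, classes = 0:1)
  expect_error(decision_scores(sub, tab2[, c("PW-2", "label")]), "PW-1",
               class = "lenci_schema_error")
})

test_that("the fusion layer learns informative scores and applies class weights", {
  withr::with_seed(4, {
    y <- rep(0:2, c(60, 25, 15))
    onehot <- diag(3)[y + 1, ] * 0.9 + 0.05
    colnames(onehot) <- paste0("s", 0:2)
    layer <- train_fusion(onehot, y, toy_params)
    p <- lencifusion:::predict_fusion_layer(layer, onehot)
    expect_identical((0:2)[max.col(p, ties.method = "first")], y)
    # uniform scores collapse to a single (weighted-prior) prediction
    flat <- matrix(1 / 3, length(y), 3,
                   dimnames = list(NULL, paste0("s", 0:2)))
    layer2 <- train_fusion(flat, y, toy_params)
    p2 <- lencifusion:::predict_fusion_layer(layer2, flat)
    expect_identical(length(unique(max.col(p2, ties.method = "first"))), 1L)
    expect_error(train_fusion(onehot, y[-1], toy_params),
                 class = "lenci_schema_error")
  })
})

test_that("fusion bookkeeping: 12 score columns, simplex output, argmax class", {
  tab <- make_toy_table(n = 140, signal = c("PW-2" = 2, "TL-1" = 2),
                        classes = 0:2, seed = 5)
  model <- build_wfusion(tab, toy_params)
  sc <- lencifusion:::concat_scores(model$submodels, tab)
  expect_identical(ncol(sc), 12L)
  expect_identical(colnames(sc)[1:4], c("PW.0", "PW.1", "PW.2", "TL.0"))
  pred <- predict(model, tab)
  probs <- as.matrix(pred[, c(".pred_0", ".pred_1", ".pred_2")])
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
  expect_identical(pred$.pred_class, (0:2)[max.col(probs, ties.method = "first")])
})

test_that("daily substitution replaces PW and TL only and is logged", {
  tab_a <- make_toy_table(n = 120, signal = c("PW-2" = 2), classes = 0:2,
                          frequency = "A", seed = 6)
  tab_b <- make_toy_table(n = 300, signal = c("PW-2" = 2), classes = 0:2,
                          frequency = "B", seed = 7)
  w <- build_wfusion(tab_a, toy_params)
  d <- build_dfusion(w, tab_b)
  expect_identical(d$variant, "dFusionModel")
  expect_identical(d$substitution_log$modality, c("PW", "TL"))
  expect_identical(d$substitution_log$to, c("daily", "daily"))
  # carried-over submodels and fusion layer are bit-identical
  for (m in c("PR", "PP")) {
    expect_identical(decision_scores(d$submodels[[m]], tab_b),
                     decision_scores(w$submodels[[m]], tab_b))
  }
  expect_identical(d$fusion, w$fusion)
  # cross-frequency prediction runs end-to-end
  expect_identical(nrow(predict(w, tab_b)), nrow(tab_b))
  # frequency mismatch is a configuration error
  expect_error(build_dfusion(w, tab_a), class = "lenci_config_error")
  expect_error(build_dfusion(list(), tab_b), class = "lenci_config_error")
})

test_that("a saved fusion model reproduces its predictions exactly", {
  tab <- make_toy_table(n = 100, classes = 0:2, seed = 8)
  model <- build_wfusion(tab, toy_params)
  dir <- withr::local_tempdir()
  save_fusion(model, dir)
  back <- load_fusion(dir)
  expect_equal(as.data.frame(predict(back, tab)),
               as.data.frame(predict(model, tab)))
  expect_identical(back$variant, model$variant)
  g <- glance(model)
  expect_identical(g$n_submodels, 4L)
  expect_identical(nrow(tidy(model)), 4L)
})
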