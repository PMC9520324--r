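#' Recipe: the multimodal fusion model
#'
#' Wraps [build_wfusion()] (and optionally the daily substitution) as a
#' [model_recipe()] for [cross_validate()].
#'
#' @param params A [fusion_params()].
#' @param classes Ordered label space.
#' @return A `model_recipe`.
#' @export
recipe_fusion <- function(params = fusion_params(), classes = 0:2) {
  model_recipe(
    name = "FusionModel",
    fit = function(table, seed) {
      p <- params; p$seed <- as.integer(seed)
      build_wfusion(table, p, classes = classes)
    },
    predict_class = function(model, table) predict(model, table)$.pred_class,
    predict_prob = function(model, table) {
      as.matrix(select(predict(model, table), -".pred_class"))
    }
  )
}

#' Recipes: traditional data-integration baselines
#'
#' Single classifiers fitted on the concatenated all-modality feature table:
#' logistic regression (LR), support vector machine (SVM), k-nearest
#' neighbours (KNN), Gaussian naive Bayes (NB), decision tree (DT), random
#' forest (RF), XGBoost, and a dummy classifier (DC) that assigns classes at
#' random respecting the class distribution.
#'
#' @param key One of `"DC"`, `"LR"`, `"SVM"`, `"KNN"`, `"NB"`, `"DT"`, `"RF"`,
#'   `"XGBoost"`.
#' @return A `model_recipe`.
#' @export
recipe_baseline <- function(key) {
  xmat <- function(table) {
    m <- feature_matrix(table)
    colnames(m) <- make.names(colnames(m))
    m
  }
  r <- switch(
    key,
    DC = model_recipe(
      "DC",
      fit = function(table, seed) {
        pr <- table(table$label) / nrow(table)
        list(classes = as.numeric(names(pr)), prob = as.numeric(pr))
      },
      predict_class = function(model, table) {
        sample(model$classes, nrow(table), replace = TRUE, prob = model$prob)
      }
    ),
    LR = model_recipe(
      "LR",
      fit = function(table, seed) {
        df <- as.data.frame(xmat(table))
        df$.label <- factor(table$label)
        nnet::multinom(.label ~ ., df, trace = FALSE, MaxNWts = 5000)
      },
      predict_class = function(model, table) {
        as.numeric(as.character(
          predict(model, as.data.frame(xmat(table)), type = "class")))
      }
    ),
    SVM = model_recipe(
      "SVM",
      fit = function(table, seed) {
        e1071::svm(xmat(table), factor(table$label))
      },
      predict_class = function(model, table) {
        as.numeric(as.character(predict(model, xmat(table))))
      }
    ),
    KNN = model_recipe(
      "KNN",
      fit = function(table, seed) {
        list(x = xmat(table), y = factor(table$label))
      },
      predict_class = function(model, table) {
        as.numeric(as.character(
          class::knn(model$x, xmat(table), model$y, k = 5)))
      }
    ),
    NB = model_recipe(
      "NB",
      fit = function(table, seed) {
        e1071::naiveBayes(as.data.frame(xmat(table)), factor(table$label))
      },
      predict_class = function(model, table) {
        as.numeric(as.character(
          predict(model, as.data.frame(xmat(table)))))
      }
    ),
    DT = model_recipe(
      "DT",
      fit = function(table, seed) {
        df <- as.data.frame(xmat(table))
        df$.label <- factor(table$label)
        rpart::rpart(.label ~ ., df, method = "class")
      },
      predict_class = function(model, table) {
        as.numeric(as.character(
          predict(model, as.data.frame(xmat(table)), type = "class")))
      }
    ),
    RF = model_recipe(
      "RF",
      fit = function(table, seed) {
        ranger::ranger(x = as.data.frame(xmat(table)),
                       y = factor(table$label), num.trees = 500,
                       seed = as.integer(seed), num.threads = 1)
      },
      predict_class = function(model, table) {
        as.numeric(as.character(
          predict(model, data = as.data.frame(xmat(table)),
                  num.threads = 1)$predictions))
      }
    ),
    XGBoost = model_recipe(
      "XGBoost",
      fit = function(table, seed) {
        cls <- sort(unique(table$label))
        d <- xgboost::xgb.DMatrix(xmat(table),
                                  label = match(table$label, cls) - 1)
        booster <- xgboost::xgb.train(
          params = list(objective = "multi:softprob",
                        num_class = length(cls), max_depth = 4, eta = 0.1,
                        nthread = 1, seed = as.integer(seed)),
          data = d, nrounds = 200, verbose = 0)
        list(booster = booster, classes = cls)
      },
      predict_class = function(model, table) {
        p <- predict(model$booster, xgboost::xgb.DMatrix(xmat(table)))
        p <- matrix(p, ncol = length(model$classes))
        model$classes[max.col(p, ties.method = "first")]
      }
    ),
    abort(sprintf("Unknown classifier key: %s", key),
          class = "lenci_config_error")
  )
  r
}

#' Compare integration baselines through the shared CV harness
#'
#' Runs each requested classifier on the concatenated all-modality feature
#' table through the identical normalise / in-fold-SMOTE / stratified-CV
#' harness used for the fusion model, and tabulates the support-weighted
#' metrics.
#'
#' @param table Feature tibble with all modality columns and `label`.
#' @param classifiers Character vector of [recipe_baseline()] keys.
#' @param k CV folds.
#' @param smote A [smote_config()] or `NULL`.
#' @param seed Seed shared across classifiers (same folds for all).
#' @return A tibble (model, mean and sd of weighted precision/recall/F2) with
#'   the full `cv_report` objects in the `reports` attribute.
#' @export
integration_baselines <- function(table,
                                  classifiers = c("DC", "LR", "SVM", "KNN",
                                                  "NB", "DT", "RF", "XGBoost"),
                                  k = 10, smote = smote_config(), seed = 1) {
  reports <- lapply(stats::setNames(nm = classifiers), function(key) {
    cross_validate(recipe_baseline(key), table, k = k, smote = smote,
                   seed = seed)
  })
  out <- purrr::map_dfr(reports, function(r) {
    g <- glance(r)
    tibble(model = r$model,
           precision = g$mean_precision, precision_sd = g$sd_precision,
           recall = g$mean_recall, recall_sd = g$sd_recall,
           f2 = g$mean_f2, f2_sd = g$sd_f2)
  })
  attr(out, "reports") <- reports
  out
}
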