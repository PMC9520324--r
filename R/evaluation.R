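#' F-beta score
#'
#' `(1 + beta^2) * P * R / (beta^2 * P + R)`; with `beta = 2` (the default)
#' recall is weighted four times as heavily as precision, reflecting that a
#' missed diagnosis costs more than a false alarm. Returns 0 when precision
#' and recall are both 0 (convention).
#'
#' @param precision,recall Values in `[0, 1]`. Vectorised.
#' @param beta Recall weighting; `beta = 2` gives the F2-score
#'   `5 P R / (4 P + R)`.
#' @return Numeric vector.
#' @examples
#' f_beta(0.9, 0.9)      # 0.9
#' f_beta(0.5, 1.0)      # 0.8333
#' @export
f_beta <- function(precision, recall, beta = 2) {
  if (any(precision < 0 | precision > 1 | recall < 0 | recall > 1,
          na.rm = TRUE)) {
    abort("`precision` and `recall` must lie in [0, 1].",
          class = "lenci_domain_error")
  }
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, num / den)
}

#' Support-weighted multi-class metrics
#'
#' One-vs-rest precision, recall and F2 per label, plus their averages
#' weighted by support (the number of true instances of each label). A
#' predicted label absent from the truth is included with zero support and
#' noted.
#'
#' @param y_true,y_pred Equal-length class vectors.
#' @param classes Optional label space; defaults to the sorted union.
#' @return A `metric_report`: list with `per_label` tibble (label, support,
#'   tp/fp/fn/tn, precision, recall, f2), `weighted` one-row tibble, and the
#'   `confusion` matrix (true x predicted).
#' @export
weighted_metrics <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` lengths differ.", class = "lenci_schema_error")
  }
  classes <- classes %||% sort(unique(c(y_true, y_pred)))
  unseen <- setdiff(unique(y_pred), unique(y_true))
  if (length(unseen)) {
    inform(sprintf("Predicted label(s) with zero support in truth: %s",
                   paste(unseen, collapse = ", ")))
  }
  per <- purrr::map_dfr(classes, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    tn <- sum(y_true != cl & y_pred != cl)
    precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
    tibble(label = cl, support = tp + fn, tp = tp, fp = fp, fn = fn, tn = tn,
           precision = precision, recall = recall,
           f2 = f_beta(precision, recall))
  })
  wsum <- sum(per$support)
  weighted <- tibble(
    precision = sum(per$support * per$precision) / wsum,
    recall = sum(per$support * per$recall) / wsum,
    f2 = sum(per$support * per$f2) / wsum
  )
  confusion <- table(true = factor(y_true, classes),
                     predicted = factor(y_pred, classes))
  structure(list(per_label = per, weighted = weighted, confusion = confusion),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(x$per_label)
  cat(sprintf("weighted: precision %.4f | recall %.4f | F2 %.4f\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f2))
  invisible(x)
}

#' @export
tidy.metric_report <- function(x, ...) x$per_label

#' @export
glance.metric_report <- function(x, ...) x$weighted

#' A model-construction recipe for the cross-validation harness
#'
#' Couples a fit function with a predict function so that every model (fusion,
#' integration baselines, dummy) runs through the identical
#' normalise-SMOTE-fit harness.
#'
#' @param name Display name.
#' @param fit `function(table, seed)` returning a fitted object; `table` is a
#'   feature tibble with a `label` column.
#' @param predict_class `function(model, table)` returning predicted classes.
#' @param predict_prob Optional `function(model, table)` returning a class
#'   probability matrix.
#' @return A `model_recipe`.
#' @export
model_recipe <- function(name, fit, predict_class, predict_prob = NULL) {
  structure(list(name = name, fit = fit, predict_class = predict_class,
                 predict_prob = predict_prob), class = "model_recipe")
}

#' SMOTE settings for in-fold oversampling
#'
#' @inheritParams smote_oversample
#' @return A `smote_config` list.
#' @export
smote_config <- function(k = 5, target_ratio = "balanced",
                         direction = "toward_neighbor", seed = 1) {
  structure(list(k = k, target_ratio = target_ratio, direction = direction,
                 seed = seed), class = "smote_config")
}

# In-fold oversampling with guard rails: k is capped at (minority size - 1);
# a singleton class falls back to plain duplication.
smote_for_fold <- function(features, labels, cfg, fold_seed) {
  counts <- table(labels)
  minority <- counts[counts < max(counts)]
  if (length(minority) == 0) {
    return(list(features = as.matrix(features), labels = labels))
  }
  if (any(minority == 1)) {
    warn("Singleton class in training fold: oversampling by duplication.",
         class = "lenci_smote_fallback")
    for (cl in names(minority[minority == 1])) {
      i <- which(labels == cl)
      extra <- rep(i, max(counts) - 1)
      features <- rbind(as.matrix(features), as.matrix(features)[extra, ,
                                                                 drop = FALSE])
      labels <- c(labels, labels[extra])
    }
    counts <- table(labels)
    minority <- counts[counts < max(counts)]
    if (length(minority) == 0) {
      return(list(features = as.matrix(features), labels = labels))
    }
  }
  k_eff <- min(cfg$k, min(minority) - 1)
  if (k_eff < cfg$k) {
    warn(sprintf("SMOTE k reduced from %d to %d for a small training fold.",
                 cfg$k, k_eff), class = "lenci_smote_k_reduced")
  }
  out <- smote_oversample(features, labels, k = k_eff,
                          target_ratio = cfg$target_ratio,
                          direction = cfg$direction, seed = fold_seed)
  out
}

# Refit the per-athlete normalisation on the training part of a fold and
# apply it to both parts (fold-internal alternative to global z-scoring).
fold_normalize <- function(train, test, cont) {
  for (f in cont) {
    stats_by <- tapply(train[[f]], train$athlete_id,
                       function(v) c(mean(v), sd_pop(v)))
    overall <- c(mean(train[[f]]), sd_pop(train[[f]]))
    tx <- function(df) {
      mu <- vapply(df$athlete_id, function(a) {
        s <- stats_by[[a]]
        if (is.null(s)) overall[1] else s[1]
      }, numeric(1))
      sg <- vapply(df$athlete_id, function(a) {
        s <- stats_by[[a]]
        if (is.null(s) || s[2] == 0) max(overall[2], 1e-12) else s[2]
      }, numeric(1))
      (df[[f]] - mu) / sg
    }
    test[[f]] <- tx(test)
    train[[f]] <- tx(train)
  }
  list(train = train, test = test)
}

#' Stratified k-fold cross-validation with in-fold SMOTE
#'
#' Splits rows into stratified folds (per-class fold sizes differ by at most
#' one), oversamples only the training part of each fold, fits the recipe and
#' scores the held-out part with support-weighted metrics. Validation rows are
#' never resampled or modified.
#'
#' @param recipe A [model_recipe()].
#' @param table Feature tibble with the encoding columns and a `label` column.
#' @param k Number of folds (default 10). If a class has fewer than `k`
#'   members, `k` is reduced with a warning (or an error in strict mode).
#' @param smote A [smote_config()], or `NULL` to skip oversampling.
#' @param seed Seed for fold assignment and all in-fold randomness.
#' @param normalize `"global"` (features already normalised) or `"fold"`
#'   (refit per-athlete z-scores on each training fold).
#' @param grouped Assign folds by athlete instead of by row, so no athlete
#'   appears in both parts of a fold.
#' @param strict Error instead of reducing `k`.
#' @return A `cv_report`: per-fold weighted metrics, per-label fold metrics,
#'   pooled confusion matrix, and a mean/sd summary.
#' @export
cross_validate <- function(recipe, table, k = 10, smote = smote_config(),
                           seed = 1, normalize = c("global", "fold"),
                           grouped = FALSE, strict = FALSE) {
  normalize <- match.arg(normalize)
  classes <- sort(unique(table$label))
  min_class <- min(table(table$label))
  if (min_class < k && !grouped) {
    if (strict) {
      abort(sprintf("Smallest class has %d members; k = %d folds impossible.",
                    min_class, k), class = "lenci_config_error")
    }
    warn(sprintf("Reducing k from %d to %d (smallest class size).", k,
                 min_class), class = "lenci_k_reduced")
    k <- min_class
  }
  feat_cols <- intersect(FEATURE_NAMES, names(table))
  cont <- setdiff(feat_cols, "PW-1")
  withr::with_seed(as.integer(seed), {
    fold <- if (grouped) {
      ath <- unique(table$athlete_id)
      af <- stats::setNames(rep_len(sample.int(k), length(ath)), sample(ath))
      unname(af[table$athlete_id])
    } else {
      stratified_folds(table$label, k)
    }
    fold_rows <- list(); per_label <- list()
    conf <- NULL
    for (f in sort(unique(fold))) {
      train <- table[fold != f, ]
      test <- table[fold == f, ]
      if (normalize == "fold") {
        nz <- fold_normalize(train, test, cont)
        train <- nz$train; test <- nz$test
      }
      if (!is.null(smote)) {
        res <- smote_for_fold(train[, feat_cols], train$label, smote,
                              fold_seed = smote$seed + f)
        train_fit <- as_tibble(as.data.frame(res$features,
                                             check.names = FALSE))
        train_fit$label <- res$labels
        attr(train_fit, "frequency") <- attr(table, "frequency")
      } else {
        train_fit <- train
      }
      model <- recipe$fit(train_fit, seed + f)
      pred <- recipe$predict_class(model, test)
      rep_f <- weighted_metrics(test$label, pred, classes = classes)
      fold_rows[[f]] <- dplyr::bind_cols(tibble(fold = f), rep_f$weighted)
      per_label[[f]] <- mutate(rep_f$per_label, fold = f)
      conf <- if (is.null(conf)) rep_f$confusion else conf + rep_f$confusion
    }
    folds <- bind_rows(fold_rows)
    summary <- tibble(
      metric = c("precision", "recall", "f2"),
      mean = c(mean(folds$precision), mean(folds$recall), mean(folds$f2)),
      sd = c(sd(folds$precision), sd(folds$recall), sd(folds$f2))
    )
    structure(list(model = recipe$name, k = k, folds = folds,
                   per_label = bind_rows(per_label), confusion = conf,
                   summary = summary),
              class = "cv_report")
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d folds\n", x$model, x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  weighted %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i],
                s$sd[i]))
  }
  invisible(x)
}

#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @export
glance.cv_report <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Net benefit at a threshold probability
#'
#' Binarised decision analysis: a row is called positive when its predicted
#' risk `p` is at least the threshold `p_t`. Net benefit of treating the
#' predicted positives is `TP/n - FP/n * p_t / (1 - p_t)`; of leaving the
#' predicted negatives untreated, `TN/n - FN/n * (1 - p_t) / p_t`; of treating
#' everyone, `(TP + FN)/n - (TN + FP)/n * p_t / (1 - p_t)` (zero exactly at
#' `p_t` = prevalence).
#'
#' @param y_true Binary outcome vector (0/1 or logical).
#' @param p Predicted positive-class probabilities.
#' @param p_t Threshold probability in (0, 1).
#' @return One-row tibble: `p_t`, `treated`, `untreated`, `treat_all`.
#' @export
net_benefit <- function(y_true, p, p_t) {
  if (p_t <= 0 || p_t >= 1) {
    abort("`p_t` must lie strictly inside (0, 1).",
          class = "lenci_domain_error")
  }
  y <- as.integer(y_true)
  n <- length(y)
  pos <- p >= p_t
  tp <- sum(pos & y == 1); fp <- sum(pos & y == 0)
  tn <- sum(!pos & y == 0); fn <- sum(!pos & y == 1)
  odds <- p_t / (1 - p_t)
  tibble(
    p_t = p_t,
    treated = tp / n - fp / n * odds,
    untreated = tn / n - fn / n / odds,
    treat_all = (tp + fn) / n - (tn + fp) / n * odds
  )
}

#' Decision curve of a fusion model
#'
#' Evaluates [net_benefit()] over a threshold grid, binarising the multi-class
#' model as positive = any predicted injury risk, with risk score
#' `p_i = 1 - P(non-injured)`.
#'
#' @param model A `fusion_model`.
#' @param table Feature table with a `label` column.
#' @param p_t_grid Threshold grid inside (0, 1).
#' @return A `net_benefit_curve` tibble with columns `p_t`, `treated`,
#'   `untreated`, `treat_all`; prevalence stored as an attribute.
#' @export
dca_curve <- function(model, table, p_t_grid = seq(0.01, 0.99, by = 0.01)) {
  if (length(p_t_grid) == 0) {
    abort("`p_t_grid` must be non-empty.", class = "lenci_domain_error")
  }
  pred <- predict(model, table)
  p_i <- 1 - pred$.pred_0
  net_benefit_curve(table$label > 0, p_i, p_t_grid)
}

#' @rdname dca_curve
#' @param y_true Binary outcomes (used by the probability-level interface).
#' @param p_i Predicted risk scores.
#' @export
net_benefit_curve <- function(y_true, p_i, p_t_grid = seq(0.01, 0.99, 0.01)) {
  out <- purrr::map_dfr(p_t_grid, function(t) net_benefit(y_true, p_i, t))
  structure(out, class = c("net_benefit_curve", class(out)),
            prevalence = mean(as.integer(y_true)))
}

#' Welch comparison of fold-level performance
#'
#' Welch's t-test for two models, Welch's ANOVA (`oneway.test`, unequal
#' variances) for more, on fold-level metric values. Significance bands:
#' p < 0.01 highly significant, < 0.05 significant, < 0.1 marginally
#' significant, otherwise not significant.
#'
#' @param ... Two or more numeric vectors of fold-level metrics, ideally named.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, `band`.
#' @export
compare_models <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]]) &&
      !is.numeric(groups[[1]])) {
    groups <- groups[[1]]
  }
  if (length(groups) < 2) {
    abort("Need at least two groups of fold metrics.",
          class = "lenci_domain_error")
  }
  if (any(lengths(groups) < 2)) {
    abort("Each group needs at least two folds.", class = "lenci_domain_error")
  }
  res <- if (length(groups) == 2) {
    tryCatch({
      ht <- t.test(groups[[1]], groups[[2]], var.equal = FALSE)
      tibble(test = "Welch t-test", statistic = unname(ht$statistic),
             df = unname(ht$parameter), p_value = ht$p.value)
    }, error = function(e) {
      tibble(test = "Welch t-test", statistic = NA_real_, df = NA_real_,
             p_value = NA_real_)
    })
  } else {
    df <- tibble(value = unlist(groups),
                 group = rep(seq_along(groups), lengths(groups)))
    tryCatch({
      ht <- oneway.test(value ~ group, data = df, var.equal = FALSE)
      tibble(test = "Welch ANOVA", statistic = unname(ht$statistic),
             df = unname(ht$parameter[2]), p_value = ht$p.value)
    }, error = function(e) {
      tibble(test = "Welch ANOVA", statistic = NA_real_, df = NA_real_,
             p_value = NA_real_)
    })
  }
  res$band <- significance_band(res$p_value)
  res
}

significance_band <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "undefined",
    p < 0.01 ~ "highly significant",
    p < 0.05 ~ "significant",
    p < 0.1 ~ "marginally significant",
    TRUE ~ "not significant"
  )
}
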