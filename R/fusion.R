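#' Hyperparameters for submodels and the fusion layer
#'
#' The gradient-boosted submodels and the random-forest fusion layer are fully
#' configurable; defaults are 200 trees of depth 4 at learning rate 0.1 for
#' each submodel and a 500-tree forest for the fusion layer. `score_mode`
#' controls which decision scores the fusion layer is trained on:
#' out-of-fold scores (default; avoids stacking leakage) or in-sample scores.
#'
#' @param submodel_nrounds,submodel_max_depth,submodel_eta XGBoost submodel
#'   boosting rounds, tree depth and learning rate.
#' @param fusion_num_trees Trees in the fusion random forest.
#' @param score_mode `"out_of_fold"` or `"in_sample"`.
#' @param oof_folds Internal folds used to produce out-of-fold scores.
#' @param seed Seed used by every stochastic component.
#' @return A `fusion_params` list.
#' @export
fusion_params <- function(submodel_nrounds = 200, submodel_max_depth = 4,
                          submodel_eta = 0.1, fusion_num_trees = 500,
                          score_mode = c("out_of_fold", "in_sample"),
                          oof_folds = 5, seed = 1) {
  stopifnot(submodel_nrounds >= 1, submodel_max_depth >= 1,
            submodel_eta > 0, fusion_num_trees >= 1, oof_folds >= 2)
  structure(list(
    submodel_nrounds = submodel_nrounds,
    submodel_max_depth = submodel_max_depth,
    submodel_eta = submodel_eta,
    fusion_num_trees = fusion_num_trees,
    score_mode = match.arg(score_mode),
    oof_folds = oof_folds,
    seed = as.integer(seed)
  ), class = "fusion_params")
}

# Stratified fold assignment: per-class fold sizes differ by at most one.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (idx in split(seq_along(labels), labels)) {
    fold[sample(idx)] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Train a unimodal gradient-boosted submodel
#'
#' Fits an XGBoost multi-class classifier on one modality's feature block.
#'
#' @param table A `modal_feature_table` (training rows only).
#' @param modality `"PW"`, `"TL"`, `"PR"` or `"PP"`.
#' @param params A [fusion_params()].
#' @param weights Optional named per-class weights applied as sample weights.
#' @param classes Ordered label space (default the three realised severity
#'   classes 0, 1, 2).
#' @return A `lenci_submodel`.
#' @export
train_submodel <- function(table, modality, params = fusion_params(),
                           weights = NULL, classes = 0:2) {
  x <- feature_matrix(table, modality)
  y <- table$label
  if (length(unique(y)) < 2) {
    abort("Training labels contain a single class.",
          class = "lenci_training_error")
  }
  if (!all(y %in% classes)) {
    abort("Labels outside the declared class space.",
          class = "lenci_schema_error")
  }
  w <- if (!is.null(weights)) unname(weights[as.character(y)]) else NULL
  dtrain <- xgboost::xgb.DMatrix(x, label = match(y, classes) - 1,
                                 weight = w)
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = length(classes),
                  max_depth = params$submodel_max_depth,
                  eta = params$submodel_eta, nthread = 1, seed = params$seed),
    data = dtrain, nrounds = params$submodel_nrounds, verbose = 0
  )
  structure(list(booster = booster, modality = modality,
                 frequency = attr(table, "frequency") %||% NA_character_,
                 features = colnames(x), classes = classes, params = params),
            class = "lenci_submodel")
}

#' Decision scores of a submodel
#'
#' The submodel's class-probability vector for each row: the "decision scores"
#' that the fusion layer consumes.
#'
#' @param model A `lenci_submodel`.
#' @param rows Data frame carrying the submodel's feature columns.
#' @return Numeric matrix, rows x classes; columns named by class.
#' @export
decision_scores <- function(model, rows) {
  missing <- setdiff(model$features, names(rows))
  if (length(missing)) {
    abort(sprintf("Rows are missing submodel feature(s): %s",
                  paste(missing, collapse = ", ")),
          class = "lenci_schema_error")
  }
  x <- as.matrix(rows[, model$features])
  p <- predict(model$booster, xgboost::xgb.DMatrix(x))
  p <- matrix(p, ncol = length(model$classes))
  colnames(p) <- as.character(model$classes)
  p
}

# Out-of-fold decision scores for one modality: the fusion layer never sees a
# score produced by a submodel that was trained on the same row. With an
# extremely rare class the fold count shrinks; if a fold's training part
# still collapses to one class, that fold falls back to in-sample scores.
oof_scores <- function(table, modality, params, classes) {
  k <- max(2, min(params$oof_folds, min(table(table$label))))
  fold <- withr::with_seed(params$seed + 77L,
                           stratified_folds(table$label, k))
  scores <- matrix(NA_real_, nrow(table), length(classes))
  full <- NULL
  for (f in sort(unique(fold))) {
    train <- table[fold != f, ]
    if (length(unique(train$label)) < 2) {
      warn("Out-of-fold training collapsed to one class; using in-sample scores for this fold.",
           class = "lenci_oof_fallback")
      if (is.null(full)) full <- train_submodel(table, modality, params,
                                                classes = classes)
      scores[fold == f, ] <- decision_scores(full, table[fold == f, ])
    } else {
      sub <- train_submodel(train, modality, params, classes = classes)
      scores[fold == f, ] <- decision_scores(sub, table[fold == f, ])
    }
  }
  colnames(scores) <- as.character(classes)
  scores
}

#' Train the decision-score fusion layer
#'
#' A probability random forest over the concatenated submodel decision scores,
#' with per-sample class weights `n_sample / (n_class * N_c)` countering label
#' imbalance.
#'
#' @param scores Matrix of concatenated decision scores (training rows only).
#' @param labels Severity labels for the score rows.
#' @param params A [fusion_params()].
#' @param weights Optional named class weights; computed by [class_weights()]
#'   from `labels` when omitted.
#' @param classes Ordered label space.
#' @return A `lenci_fusion_layer`.
#' @export
train_fusion <- function(scores, labels, params = fusion_params(),
                         weights = NULL, classes = 0:2) {
  if (nrow(scores) != length(labels)) {
    abort("`scores` rows and `labels` length differ.",
          class = "lenci_schema_error")
  }
  weights <- weights %||% class_weights(labels)
  df <- as.data.frame(scores)
  names(df) <- make.names(colnames(scores) %||% seq_len(ncol(scores)),
                          unique = TRUE)
  forest <- ranger::ranger(
    x = df, y = factor(labels, levels = classes),
    probability = TRUE, num.trees = params$fusion_num_trees,
    case.weights = unname(weights[as.character(labels)]),
    seed = params$seed, num.threads = 1
  )
  structure(list(forest = forest, classes = classes,
                 feature_names = names(df)),
            class = "lenci_fusion_layer")
}

predict_fusion_layer <- function(layer, scores) {
  df <- as.data.frame(scores)
  names(df) <- layer$feature_names
  p <- predict(layer$forest, data = df, num.threads = 1)$predictions
  # classes absent from the training labels get probability zero
  out <- matrix(0, nrow(p), length(layer$classes),
                dimnames = list(NULL, as.character(layer$classes)))
  out[, colnames(p)] <- p
  out
}

concat_scores <- function(submodels, rows) {
  blocks <- lapply(names(MODALITIES), function(m) {
    s <- decision_scores(submodels[[m]], rows)
    colnames(s) <- paste(m, colnames(s), sep = ".")
    s
  })
  do.call(cbind, blocks)
}

#' Build the weekly fusion model (wFusionModel)
#'
#' Trains one gradient-boosted submodel per modality on the weekly feature
#' table and fuses their decision scores (concatenated in the order PW, TL,
#' PR, PP) with a class-weighted random forest.
#'
#' @param table_a Weekly `modal_feature_table` (frequency `"A"`).
#' @param params A [fusion_params()].
#' @param classes Ordered label space.
#' @return A `fusion_model` with variant `"wFusionModel"`.
#' @export
build_wfusion <- function(table_a, params = fusion_params(), classes = 0:2) {
  submodels <- lapply(stats::setNames(nm = names(MODALITIES)), function(m) {
    train_submodel(table_a, m, params, classes = classes)
  })
  scores <- if (params$score_mode == "out_of_fold") {
    blocks <- lapply(names(MODALITIES), function(m) {
      s <- oof_scores(table_a, m, params, classes)
      colnames(s) <- paste(m, colnames(s), sep = ".")
      s
    })
    do.call(cbind, blocks)
  } else {
    concat_scores(submodels, table_a)
  }
  fusion <- train_fusion(scores, table_a$label, params, classes = classes)
  structure(list(
    submodels = submodels, fusion = fusion, variant = "wFusionModel",
    classes = classes, params = params,
    substitution_log = tibble(modality = character(), from = character(),
                              to = character())
  ), class = "fusion_model")
}

#' Substitute daily submodels into a weekly fusion model (dFusionModel)
#'
#' Retrains the perceived-wellness (PW) and training-load (TL) submodels at
#' daily frequency and substitutes them into a trained wFusionModel. The
#' physiological-response and physical-performance submodels and, by default,
#' the fusion layer are carried over unchanged; the substitution is logged.
#'
#' @param parent A trained `fusion_model` (the wFusionModel).
#' @param table_b Daily `modal_feature_table` (frequency `"B"`).
#' @param params A [fusion_params()]; defaults to the parent's.
#' @param refit_fusion Refit the fusion layer on the daily table's decision
#'   scores instead of carrying it over.
#' @return A `fusion_model` with variant `"dFusionModel"`.
#' @export
build_dfusion <- function(parent, table_b, params = parent$params,
                          refit_fusion = FALSE) {
  if (!inherits(parent, "fusion_model")) {
    abort("`parent` must be a trained fusion_model.",
          class = "lenci_config_error")
  }
  freq <- attr(table_b, "frequency")
  if (!is.null(freq) && freq != "B") {
    abort("dFusionModel substitution requires a daily (frequency B) table.",
          class = "lenci_config_error")
  }
  model <- parent
  for (m in c("PW", "TL")) {
    model$submodels[[m]] <- train_submodel(table_b, m, params,
                                           classes = parent$classes)
  }
  model$substitution_log <- tibble(
    modality = c("PW", "TL"), from = "weekly", to = "daily"
  )
  if (refit_fusion) {
    scores <- concat_scores(model$submodels, table_b)
    model$fusion <- train_fusion(scores, table_b$label, params,
                                 classes = parent$classes)
  }
  model$variant <- "dFusionModel"
  model$params <- params
  model
}

#' Predict severity classes and probabilities from a fusion model
#'
#' @param object A `fusion_model`.
#' @param newdata Data frame carrying all modalities' feature columns.
#' @param ... Unused.
#' @return Tibble with `.pred_class` (fusion argmax) and one `.pred_<class>`
#'   probability column per severity class.
#' @export
predict.fusion_model <- function(object, newdata, ...) {
  scores <- concat_scores(object$submodels, newdata)
  p <- predict_fusion_layer(object$fusion, scores)
  cls <- object$classes[max.col(p, ties.method = "first")]
  out <- as_tibble(p, .name_repair = ~ paste0(".pred_", .x))
  out$.pred_class <- cls
  select(out, ".pred_class", dplyr::everything())
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf("<fusion_model> %s | classes: %s | fusion: %d-tree RF\n",
              x$variant, paste(x$classes, collapse = ","),
              x$params$fusion_num_trees))
  for (m in names(x$submodels)) {
    s <- x$submodels[[m]]
    cat(sprintf("  %s submodel (%s): %d features, %d rounds\n", m,
                s$frequency, length(s$features), s$params$submodel_nrounds))
  }
  if (nrow(x$substitution_log)) {
    cat("  substitutions:",
        paste(sprintf("%s %s->%s", x$substitution_log$modality,
                      x$substitution_log$from, x$substitution_log$to),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.fusion_model <- function(x, ...) {
  tibble(
    modality = names(x$submodels),
    frequency = vapply(x$submodels, function(s) s$frequency, character(1)),
    n_features = vapply(x$submodels, function(s) length(s$features),
                        integer(1)),
    nrounds = vapply(x$submodels,
                     function(s) s$params$submodel_nrounds, numeric(1))
  )
}

#' @export
glance.fusion_model <- function(x, ...) {
  tibble(variant = x$variant, n_submodels = length(x$submodels),
         n_classes = length(x$classes),
         fusion_trees = x$params$fusion_num_trees,
         score_mode = x$params$score_mode, seed = x$params$seed)
}

#' Save / load a fusion model bundle
#'
#' Serialises the submodel boosters, the fusion forest and a JSON manifest
#' (variant, classes, hyperparameters, substitution log) into a directory.
#' Loading reproduces predictions exactly.
#'
#' @param model A `fusion_model`.
#' @param directory Target directory.
#' @return `save_fusion()` the directory, invisibly; `load_fusion()` the model.
#' @export
save_fusion <- function(model, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (m in names(model$submodels)) {
    xgboost::xgb.save(model$submodels[[m]]$booster,
                      file.path(directory, paste0(m, ".ubj")))
  }
  saveRDS(model$fusion, file.path(directory, "fusion.rds"))
  manifest <- list(
    variant = model$variant, classes = model$classes,
    params = unclass(model$params),
    substitution_log = model$substitution_log,
    submodels = lapply(model$submodels, function(s) {
      list(modality = s$modality, frequency = s$frequency,
           features = s$features)
    })
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(directory)
}

#' @rdname save_fusion
#' @export
load_fusion <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  params <- do.call(fusion_params, manifest$params)
  classes <- manifest$classes
  submodels <- lapply(stats::setNames(nm = names(MODALITIES)), function(m) {
    structure(list(
      booster = xgboost::xgb.load(file.path(directory, paste0(m, ".ubj"))),
      modality = m, frequency = manifest$submodels[[m]]$frequency,
      features = manifest$submodels[[m]]$features,
      classes = classes, params = params
    ), class = "lenci_submodel")
  })
  structure(list(
    submodels = submodels,
    fusion = readRDS(file.path(directory, "fusion.rds")),
    variant = manifest$variant, classes = classes, params = params,
    substitution_log = as_tibble(manifest$substitution_log)
  ), class = "fusion_model")
}
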