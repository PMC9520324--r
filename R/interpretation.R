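#' Per-class SHAP values of a submodel
#'
#' TreeSHAP attributions from the gradient-boosted submodel (the established
#' tree explainer built into XGBoost), per severity class; the bias column is
#' dropped.
#'
#' @param model A `lenci_submodel`.
#' @param rows Data frame carrying the submodel's features.
#' @return Named list, one samples x features matrix per class.
#' @export
submodel_shap <- function(model, rows) {
  x <- as.matrix(rows[, model$features])
  contrib <- predict(model$booster, xgboost::xgb.DMatrix(x),
                     predcontrib = TRUE)
  # n x classes x (features + bias)
  out <- lapply(seq_along(model$classes), function(ci) {
    m <- contrib[, ci, seq_along(model$features), drop = TRUE]
    m <- matrix(m, ncol = length(model$features))
    colnames(m) <- model$features
    m
  })
  stats::setNames(out, as.character(model$classes))
}

#' Mean absolute SHAP weights
#'
#' Aggregates a samples x features SHAP matrix into per-feature absolute
#' weights (column means of absolute values) and relative weights (each
#' feature's share of the total).
#'
#' @param shap_values Numeric samples x features matrix.
#' @return Tibble: `feature`, `mean_abs_shap`, `relative_weight` (sums to 1
#'   unless all weights are zero).
#' @examples
#' mean_abs_shap(matrix(c(1, -3, -1, 1), 2, dimnames = list(NULL, c("a", "b"))))
#' @export
mean_abs_shap <- function(shap_values) {
  m <- as.matrix(shap_values)
  if (length(m) == 0) {
    abort("`shap_values` must be non-empty.", class = "lenci_domain_error")
  }
  w <- colMeans(abs(m))
  tot <- sum(w)
  tibble(
    feature = colnames(m) %||% as.character(seq_along(w)),
    mean_abs_shap = unname(w),
    relative_weight = if (tot == 0) rep(0, length(w)) else unname(w) / tot
  )
}

#' Monte-Carlo sampling Shapley values
#'
#' Model-agnostic Shapley attribution by sampled feature permutations with
#' marginal (background-row) imputation. Used to attribute the fusion layer's
#' prediction to its submodel decision-score inputs, for which no tree-path
#' explainer applies.
#'
#' @param f Prediction function: matrix of rows -> matrix (rows x classes).
#' @param x Numeric matrix of rows to explain (also the background sample).
#' @param nsim Number of sampled permutations.
#' @param seed Seed.
#' @return Array rows x features x classes of Shapley estimates.
#' @export
sampling_shap <- function(f, x, nsim = 30, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  base <- f(x)
  n_cls <- ncol(base)
  phi <- array(0, dim = c(n, p, n_cls))
  withr::with_seed(as.integer(seed), {
    for (t in seq_len(nsim)) {
      perm <- sample.int(p)
      bg <- sample.int(n, n, replace = TRUE)
      z <- x[bg, , drop = FALSE]
      prev <- f(z)
      for (j in perm) {
        z[, j] <- x[, j]
        cur <- f(z)
        phi[, j, ] <- phi[, j, ] + (cur - prev)
        prev <- cur
      }
    }
  })
  phi <- phi / nsim
  dimnames(phi) <- list(NULL, colnames(x), colnames(base))
  phi
}

#' Relative weight of each submodel in the fusion layer
#'
#' Attributes the fusion forest's class probabilities to the concatenated
#' decision-score inputs via [sampling_shap()], groups the attributions by the
#' originating submodel (sum of member-column mean absolute SHAP), and
#' normalises within each class.
#'
#' @param fusion A trained `fusion_model`.
#' @param rows Feature table to explain.
#' @param nsim Sampled permutations for the Shapley estimate.
#' @param seed Seed.
#' @return A `weight_table` tibble: `class`, `submodel`, `mean_abs_shap`,
#'   `relative_weight` (sums to 1 within class). Per-sample grouped
#'   attributions are kept in the `per_sample` attribute (one samples x
#'   submodels matrix per class) for downstream Welch tests.
#' @export
submodel_weights <- function(fusion, rows, nsim = 30, seed = 1) {
  if (!inherits(fusion, "fusion_model")) {
    abort("`fusion` must be a trained fusion_model.", class = "lenci_state_error")
  }
  scores <- concat_scores(fusion$submodels, rows)
  f <- function(m) predict_fusion_layer(fusion$fusion, m)
  phi <- sampling_shap(f, scores, nsim = nsim, seed = seed)
  groups <- sub("\\..*$", "", colnames(scores))
  per_sample <- list()
  out <- purrr::map_dfr(seq_along(fusion$classes), function(ci) {
    cl <- fusion$classes[ci]
    absphi <- abs(phi[, , ci, drop = FALSE][, , 1])
    gm <- vapply(names(MODALITIES), function(g) {
      rowSums(absphi[, groups == g, drop = FALSE])
    }, numeric(nrow(absphi)))
    per_sample[[as.character(cl)]] <<- gm
    w <- colMeans(gm)
    tibble(class = cl, submodel = names(MODALITIES),
           mean_abs_shap = unname(w),
           relative_weight = if (sum(w) == 0) rep(0, length(w)) else
             unname(w) / sum(w))
  })
  structure(out, class = c("weight_table", class(out)),
            per_sample = per_sample)
}

#' Welch tests on per-sample weights across severity classes
#'
#' For every item (feature or submodel), Welch's t-test of each injury class's
#' per-sample values against the non-injured reference, plus Welch's ANOVA
#' across all classes, with the significance bands used throughout
#' (p < 0.01 highly significant, < 0.05 significant, < 0.1 marginal).
#'
#' @param values_by_class Named list: class -> samples x items matrix
#'   (per-sample SHAP values or grouped weights).
#' @param reference Name of the reference (non-injured) class.
#' @return Tibble: `item`, `comparison`, `test`, `statistic`, `p_value`,
#'   `band`.
#' @export
weight_difference_tests <- function(values_by_class, reference = "0") {
  if (!reference %in% names(values_by_class)) {
    abort("`reference` class not present.", class = "lenci_config_error")
  }
  items <- colnames(values_by_class[[reference]])
  others <- setdiff(names(values_by_class), reference)
  purrr::map_dfr(items, function(it) {
    ref_v <- values_by_class[[reference]][, it]
    rows <- purrr::map_dfr(others, function(cl) {
      v <- values_by_class[[cl]][, it]
      res <- compare_models(v, ref_v)
      tibble(item = it, comparison = paste(cl, "vs", reference),
             test = res$test, statistic = res$statistic,
             p_value = res$p_value, band = res$band)
    })
    if (length(values_by_class) > 2) {
      res <- compare_models(lapply(values_by_class, function(m) m[, it]))
      rows <- bind_rows(rows, tibble(
        item = it, comparison = "all classes", test = res$test,
        statistic = res$statistic, p_value = res$p_value, band = res$band))
    }
    rows
  })
}

#' Build a SHAP risk network for one severity class
#'
#' Nodes are the monitoring features; node statistics are Welch t values of
#' the feature's per-sample SHAP values in the target class against the
#' non-injured reference (zero, the standard size, when the target is the
#' reference itself). Edges are Spearman correlations between features'
#' per-sample SHAP columns within the target class, kept when the absolute
#' correlation reaches the threshold. Positive statistics yield
#' larger-than-standard nodes.
#'
#' @param shap_by_class Named list: class -> samples x features SHAP matrix.
#' @param target_class Class whose network to build.
#' @param reference_class Reference (non-injured) class.
#' @param edge_threshold Keep edges with `|rho| >=` this value.
#' @return A `risk_network`: list with `nodes` (feature, modality, statistic,
#'   size) and `edges` (from, to, rho) tibbles.
#' @export
build_network <- function(shap_by_class, target_class, reference_class = "0",
                          edge_threshold = 0.3) {
  target_class <- as.character(target_class)
  reference_class <- as.character(reference_class)
  m_t <- shap_by_class[[target_class]]
  m_r <- shap_by_class[[reference_class]]
  if (is.null(m_t) || is.null(m_r)) {
    abort("Target or reference class missing from `shap_by_class`.",
          class = "lenci_config_error")
  }
  if (nrow(m_t) < 3) {
    abort("At least 3 samples are needed for Spearman correlations.",
          class = "lenci_domain_error")
  }
  feats <- colnames(m_t)
  stat <- if (target_class == reference_class) {
    rep(0, length(feats))
  } else {
    vapply(feats, function(f) {
      res <- compare_models(m_t[, f], m_r[, f])
      if (is.na(res$statistic)) 0 else res$statistic
    }, numeric(1))
  }
  nodes <- tibble(
    feature = feats, modality = feature_modality(feats),
    statistic = unname(stat),
    size = pmax(0.2, 1 + 0.2 * unname(stat))
  )
  rho <- suppressWarnings(cor(m_t, method = "spearman"))
  idx <- which(upper.tri(rho) & abs(rho) >= edge_threshold & !is.na(rho),
               arr.ind = TRUE)
  edges <- tibble(
    from = feats[idx[, 1]], to = feats[idx[, 2]],
    rho = rho[idx]
  )
  structure(list(nodes = nodes, edges = edges, target_class = target_class,
                 reference_class = reference_class,
                 edge_threshold = edge_threshold),
            class = "risk_network")
}

#' @export
print.risk_network <- function(x, ...) {
  cat(sprintf("<risk_network> class %s vs %s: %d nodes, %d edges (|rho| >= %.2f)\n",
              x$target_class, x$reference_class, nrow(x$nodes), nrow(x$edges),
              x$edge_threshold))
  invisible(x)
}

#' @export
tidy.risk_network <- function(x, ...) x$edges

#' Convert / export a risk network
#'
#' @param network A `risk_network`.
#' @param path File path for the GraphML export.
#' @return An igraph object, or (for the writer) the path invisibly.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = rename(network$nodes, name = "feature")
  )
  g
}

#' @rdname as_igraph
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
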