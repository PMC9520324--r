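#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_hline geom_point
#'   geom_segment geom_col labs theme_minimal coord_equal facet_wrap
#'   scale_size_identity position_dodge
#' @export
ggplot2::autoplot

#' Plot a decision curve
#'
#' Net benefit of the model's treat-if-risk-exceeds-threshold policy against
#' the treat-all and treat-none references over the threshold grid.
#'
#' @param object A `net_benefit_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.net_benefit_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("treated", "treat_all"),
                            names_to = "policy", values_to = "net_benefit")
  df$policy <- dplyr::recode(df$policy, treated = "model",
                             treat_all = "treat all")
  ggplot(df, aes(x = .data$p_t, y = .data$net_benefit,
                 colour = .data$policy)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    labs(x = "threshold probability", y = "net benefit",
         colour = NULL, title = "Decision curve analysis") +
    theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot of fold-level weighted precision, recall and F2.
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$folds, c("precision", "recall", "f2"),
                            names_to = "metric")
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    labs(x = NULL, y = "weighted metric",
         title = sprintf("%s: %d-fold cross-validation", object$model,
                         object$k)) +
    theme_minimal()
}

#' Plot submodel or feature weights
#'
#' @param object A `weight_table` (from [submodel_weights()]).
#' @param ... Unused.
#' @return A ggplot of relative weights per class.
#' @export
autoplot.weight_table <- function(object, ...) {
  ggplot(as_tibble(object),
         aes(x = .data$submodel, y = .data$relative_weight,
             fill = factor(.data$class))) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "relative weight", fill = "severity class") +
    theme_minimal()
}

#' Plot a SHAP risk network with concentric modality ordering
#'
#' Nodes are placed on a circle grouped by modality; node area encodes the
#' Welch statistic against the non-injured reference (standard size at zero),
#' edge opacity encodes the absolute Spearman correlation of the per-sample
#' SHAP values.
#'
#' @param object A `risk_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.risk_network <- function(object, ...) {
  nodes <- arrange(object$nodes, match(.data$modality, names(MODALITIES)))
  k <- nrow(nodes)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  nodes$x <- cos(theta); nodes$y <- sin(theta)
  edges <- object$edges |>
    left_join(select(nodes, "feature", "x", "y"),
              by = c(from = "feature")) |>
    left_join(select(nodes, "feature", "x", "y"),
              by = c(to = "feature"), suffix = c("", "_to"))
  p <- ggplot(nodes, aes(x = .data$x, y = .data$y))
  if (nrow(edges)) {
    p <- p + geom_segment(
      data = edges,
      aes(x = .data$x, y = .data$y, xend = .data$x_to, yend = .data$y_to,
          alpha = abs(.data$rho)), colour = "grey50")
  }
  p +
    geom_point(aes(size = 6 * .data$size, colour = .data$modality)) +
    ggplot2::geom_text(aes(label = .data$feature), nudge_y = 0.12, size = 3) +
    scale_size_identity() +
    coord_equal() +
    labs(title = sprintf("Risk network: class %s vs %s", object$target_class,
                         object$reference_class),
         alpha = "|Spearman rho|", colour = "modality") +
    ggplot2::theme_void()
}
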