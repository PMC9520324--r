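#' SMOTE minority oversampling
#'
#' Synthesises new minority-class rows by interpolating between a minority
#' sample `d` and one of its `k` nearest same-class neighbours `d_n`
#' (Euclidean distance): `d + u * (d_n - d)` with `u ~ U(0, 1)`
#' (`direction = "toward_neighbor"`, canonical SMOTE). The alternative
#' `direction = "as_printed"` uses `d + u * (d - d_n)`, which extrapolates
#' away from the neighbour. Majority rows are never touched; original rows are
#' preserved verbatim and synthetic rows appended.
#'
#' @param features Numeric matrix or data frame (no missing values).
#' @param labels Class vector, one per row.
#' @param k Number of nearest same-class neighbours to draw from. Every class
#'   that is oversampled must have more than `k` members.
#' @param target_ratio `"balanced"` (every class raised to the majority count)
#'   or a named vector of per-class multipliers of the original counts.
#' @param direction Interpolation direction; see above.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return List with `features` (matrix), `labels`, and a `provenance` tibble
#'   recording, for every synthetic row, the base row index, neighbour row
#'   index and interpolation draw `u`.
#' @export
smote_oversample <- function(features, labels, k = 5,
                             target_ratio = "balanced",
                             direction = c("toward_neighbor", "as_printed"),
                             seed = 1) {
  direction <- match.arg(direction)
  x <- as.matrix(features)
  if (anyNA(x)) abort("`features` must not contain missing values.",
                      class = "lenci_domain_error")
  if (nrow(x) != length(labels)) {
    abort("`features` rows and `labels` length differ.",
          class = "lenci_schema_error")
  }
  if (k < 1) abort("`k` must be >= 1.", class = "lenci_config_error")
  counts <- table(labels)
  targets <- if (identical(target_ratio, "balanced")) {
    stats::setNames(rep(max(counts), length(counts)), names(counts))
  } else {
    if (is.null(names(target_ratio)) ||
        !all(names(counts) %in% names(target_ratio))) {
      abort("`target_ratio` must be \"balanced\" or a named per-class multiplier.",
            class = "lenci_config_error")
    }
    round(counts * target_ratio[names(counts)])
  }

  withr::with_seed(as.integer(seed), {
    syn <- list(); syn_lab <- list(); prov <- list()
    for (cl in names(counts)) {
      need <- targets[[cl]] - counts[[cl]]
      if (need <= 0) next
      idx <- which(labels == cl)
      if (length(idx) <= k) {
        abort(sprintf(
          "Class %s has %d members; SMOTE with k = %d needs more than k.",
          cl, length(idx), k), class = "lenci_config_error")
      }
      dm <- as.matrix(stats::dist(x[idx, , drop = FALSE]))
      diag(dm) <- Inf
      nn <- matrix(apply(dm, 1, function(row) order(row)[seq_len(k)]),
                   nrow = k)
      base <- sample(seq_along(idx), need, replace = TRUE)
      pick <- sample.int(k, need, replace = TRUE)
      u <- runif(need)
      nb <- vapply(seq_len(need), function(i) nn[pick[i], base[i]], integer(1))
      d <- x[idx[base], , drop = FALSE]
      dn <- x[idx[nb], , drop = FALSE]
      new <- if (direction == "toward_neighbor") {
        d + u * (dn - d)
      } else {
        d + u * (d - dn)
      }
      syn[[cl]] <- new
      syn_lab[[cl]] <- rep(labels[idx[1]], need)
      prov[[cl]] <- tibble(class = cl, base = idx[base],
                           neighbor = idx[nb], u = u)
    }
    features_out <- rbind(x, do.call(rbind, syn))
    rownames(features_out) <- NULL
    list(
      features = features_out,
      labels = c(labels, unlist(syn_lab, use.names = FALSE)),
      provenance = if (length(prov)) bind_rows(prov) else
        tibble(class = character(), base = integer(),
               neighbor = integer(), u = numeric())
    )
  })
}

#' Class weights against label imbalance
#'
#' Per-class weight `n_sample / (n_class * N_c)`, where `n_sample` is the total
#' number of rows, `n_class` the number of label categories present and `N_c`
#' the count of class `c`. Balanced classes all get weight 1; the weights
#' conserve total mass: `sum_c weight_c * N_c = n_sample / n_class * n_class`.
#'
#' @param labels Class vector (non-empty).
#' @return Named numeric vector of per-class weights.
#' @examples
#' class_weights(rep(c(0, 1, 2), c(81, 5, 1)))
#' @export
class_weights <- function(labels) {
  if (length(labels) == 0) {
    abort("`labels` must be non-empty.", class = "lenci_domain_error")
  }
  counts <- table(labels)
  w <- length(labels) / (length(counts) * as.numeric(counts))
  stats::setNames(w, names(counts))
}
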