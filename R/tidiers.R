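#' Tidy a Hill dose-response fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("maxA", "halfA_conc", "HillC", "intersect"),
         estimate = c(x$maxA, x$halfA_conc, x$HillC, x$intersect))
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(residual_ss = x$residual, n_doses = nrow(x$data),
         identifiable = x$identifiable)
}

#' Tidy a classifier report
#'
#' @param x A `classifier_report`.
#' @param ... Unused.
#' @return One row per class with its F1 score.
#' @export
tidy.classifier_report <- function(x, ...) {
  tibble(class = names(x$f1), f1 = unname(x$f1),
         n = as.numeric(rowSums(x$confusion)))
}

#' @rdname tidy.classifier_report
#' @export
glance.classifier_report <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_trees = x$config$n_trees,
         max_splits = x$config$max_splits, folds = x$config$folds,
         n_cells = sum(x$confusion), seed = x$seed)
}

#' Tidy a mutual-information result
#'
#' @param x An `mi_result`.
#' @param ... Unused.
#' @return The subsample curve as a tibble (`n`, `mi_bits`).
#' @export
tidy.mi_result <- function(x, ...) x$curve

#' @rdname tidy.mi_result
#' @export
glance.mi_result <- function(x, ...) {
  tibble(mi_bits = x$mi_bits, slope = x$slope, k = x$k,
         n_subsamples = nrow(x$curve), n_total = x$n_total, seed = x$seed)
}

#' Tidy a paired correlation report
#'
#' @param x A `correlation_report`.
#' @param ... Unused.
#' @return The per-feature-pair tibble (`feature`, `cc`, `p_value`,
#'   `significant`).
#' @export
tidy.correlation_report <- function(x, ...) x$pairs

#' @rdname tidy.correlation_report
#' @export
glance.correlation_report <- function(x, ...) {
  tibble(n_cells = x$n_cells, n_pairs = nrow(x$pairs),
         n_significant = sum(x$pairs$significant, na.rm = TRUE),
         p_threshold = x$p_threshold, cc_threshold = x$cc_threshold)
}

#' Tidy an expression distribution
#'
#' @param x An `expression_distribution`.
#' @param ... Unused.
#' @return The per-mode, per-timepoint summary tibble.
#' @export
tidy.expression_distribution <- function(x, ...) x$summary
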