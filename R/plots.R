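#' Plot a set of paired activity trajectories
#'
#' Line plot of p38 and NF-kB activity over time, one faint line per cell,
#' faceted by channel (and stimulus when several are present).
#'
#' @param traj Long trajectory tibble.
#' @param max_cells Downsample to at most this many cells for legibility.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(traj, max_cells = 100, alpha = 0.25) {
  ids <- unique(traj$cell_id)
  if (length(ids) > max_cells) {
    traj <- filter(traj, .data$cell_id %in% ids[seq_len(max_cells)])
  }
  long <- traj |>
    tidyr::pivot_longer(c("p38_activity", "nfkb_activity"),
                        names_to = "channel", values_to = "activity") |>
    mutate(channel = ifelse(.data$channel == "p38_activity", "p38", "NF-kB"))
  p <- ggplot(long, aes(.data$time_min, .data$activity,
                        group = .data$cell_id)) +
    geom_line(alpha = alpha, linewidth = 0.3) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "time (min)", y = "activity") +
    theme_minimal()
  if (dplyr::n_distinct(traj$stimulus) > 1) {
    p + facet_grid(channel ~ stimulus, scales = "free_y")
  } else {
    p + facet_wrap(~channel, scales = "free_y", ncol = 1)
  }
}

#' Plot a responder-fraction dose-response table
#'
#' @param object A `dose_response` tibble from [build_dose_response()].
#' @param ... Unused.
#' @return A ggplot object with one curve per pathway on a log dose axis.
#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot(object, aes(.data$dose, .data$fraction, colour = .data$pathway)) +
    geom_point() +
    geom_line() +
    scale_x_log10() +
    labs(x = "dose", y = "responder fraction") +
    ylim(0, 1) +
    theme_minimal()
}

#' Plot a Hill fit over its dose-response data
#'
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(dose = exp(seq(log(min(d$dose)), log(max(d$dose)),
                                length.out = 200)))
  grid$fraction <- predict(object, grid$dose)
  ggplot(d, aes(.data$dose, .data$fraction)) +
    geom_point() +
    geom_line(data = grid) +
    scale_x_log10() +
    labs(x = "dose", y = "responder fraction") +
    theme_minimal()
}

#' Plot the MI subsample-extrapolation curve
#'
#' @param object An `mi_result`.
#' @param ... Unused.
#' @return A ggplot object showing MI against 1/n with the fitted line and
#'   intercept.
#' @export
autoplot.mi_result <- function(object, ...) {
  d <- object$curve |> mutate(inv_n = 1 / .data$n)
  ggplot(d, aes(.data$inv_n, .data$mi_bits)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                linetype = "dashed") +
    geom_hline(yintercept = object$mi_bits, colour = "grey50") +
    labs(x = "1 / n", y = "MI (bits)",
         subtitle = paste0("extrapolated MI = ",
                           round(object$mi_bits, 3), " bits")) +
    theme_minimal()
}

#' Heatmap of a classifier confusion matrix
#'
#' @param object A `classifier_report`.
#' @param normalize Row-normalise counts to per-class fractions.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.classifier_report <- function(object, normalize = TRUE, ...) {
  cm <- as.data.frame(object$confusion)
  if (normalize) {
    cm <- cm |>
      group_by(.data$true) |>
      mutate(Freq = .data$Freq / sum(.data$Freq)) |>
      ungroup()
  }
  ggplot(cm, aes(.data$predicted, .data$true, fill = .data$Freq)) +
    geom_tile() +
    geom_text(aes(label = round(.data$Freq, 2)), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue") +
    labs(x = "predicted", y = "true",
         subtitle = paste0("accuracy = ", round(object$accuracy, 3))) +
    theme_minimal()
}

#' Bar chart of paired feature correlations
#'
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @return A ggplot object; significant pairs (p < threshold and |CC| above
#'   threshold) are filled.
#' @export
autoplot.correlation_report <- function(object, ...) {
  d <- object$pairs
  ggplot(d, aes(stats::reorder(.data$feature, .data$cc), .data$cc,
                fill = .data$significant)) +
    geom_col() +
    coord_flip() +
    scale_fill_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey70")) +
    labs(x = NULL, y = "Spearman CC (p38 vs NF-kB)") +
    theme_minimal()
}
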