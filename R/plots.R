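state_fill_scale <- function() {
  ggplot2::scale_fill_manual(values = c(REM = "#d1495b", Wake = "#edae49",
                                        NREM = "#00798c"), drop = FALSE)
}

state_color_scale <- function() {
  ggplot2::scale_colour_manual(values = c(REM = "#d1495b", Wake = "#edae49",
                                          NREM = "#00798c"), drop = FALSE)
}

#' Confusion-matrix heatmap
#'
#' Row-normalized percentages, truth on rows, prediction on columns.
#'
#' @param object a `remloop_confusion`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.remloop_confusion <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted,
                                  y = factor(.data$truth, levels = rev(vigilance_states())),
                                  fill = .data$row_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$row_pct)),
                       colour = "white", fontface = "bold", na.rm = TRUE) +
    ggplot2::scale_fill_gradient(low = "#2c3e50", high = "#d1495b",
                                 limits = c(0, 100), name = "% of true class") +
    ggplot2::labs(x = "Predicted state", y = "True state") +
    ggplot2::theme_minimal()
}

#' State-space scatter: theta/delta ratio vs EMG RMS
#'
#' The two-dimensional feature space in which REM epochs form a distinct
#' high-theta/low-EMG cluster under baseline conditions.
#'
#' @param export table from [state_space_export()].
#' @param log_axes plot both axes on log10 scales.
#' @return a ggplot.
#' @export
plot_state_space <- function(export, log_axes = TRUE) {
  p <- ggplot2::ggplot(export, ggplot2::aes(x = .data$r_theta_delta,
                                            y = .data$emg_rms,
                                            colour = .data$state)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    state_color_scale() +
    ggplot2::labs(x = expression(theta / delta ~ "ratio"),
                  y = "EMG RMS (mV)", colour = "State") +
    ggplot2::theme_minimal()
  if (log_axes) p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  p
}

#' Closed-loop session overview
#'
#' Epoch-level hypnogram ribbons (plant truth and classifier prediction)
#' over the TTL trigger raster.
#'
#' @param object a `remloop_session`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.remloop_session <- function(object, ...) {
  ep <- object$epochs |>
    tidyr::pivot_longer(c("predicted", "truth"), names_to = "source",
                        values_to = "state")
  trig <- object$cycles[object$cycles$trigger == "high", "time_s"]
  p <- ggplot2::ggplot(ep, ggplot2::aes(x = .data$start_s / 60, y = .data$source,
                                        fill = .data$state)) +
    ggplot2::geom_tile(height = 0.8) +
    state_fill_scale() +
    ggplot2::labs(x = "Time (min)", y = NULL, fill = "State") +
    ggplot2::theme_minimal()
  if (nrow(trig) > 0) {
    p <- p + ggplot2::geom_rug(data = trig,
                               ggplot2::aes(x = .data$time_s / 60),
                               inherit.aes = FALSE, sides = "b",
                               colour = "#d1495b", alpha = 0.5, length = ggplot2::unit(0.04, "npc"))
  }
  p
}

#' Occupancy and fold-change panels of an efficacy report
#'
#' Left: mean state occupancy under baseline vs deprivation. Right:
#' per-state geometric-mean baseline-to-deprivation fold change with
#' bootstrap CI, on a log scale.
#'
#' @param object a `remloop_efficacy`.
#' @param ... unused.
#' @return a ggplot (faceted).
#' @export
autoplot.remloop_efficacy <- function(object, ...) {
  d <- object$per_state |>
    dplyr::select("state", "fold_gm", "fold_ci_lo", "fold_ci_hi")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$state, y = .data$fold_gm,
                                  fill = .data$state)) +
    ggplot2::geom_col(width = 0.6, show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold_ci_lo,
                                        ymax = .data$fold_ci_hi), width = 0.2) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    state_fill_scale() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "Baseline / RSD occupancy (geometric mean)") +
    ggplot2::theme_minimal()
}
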