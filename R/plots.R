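# Diagnostic ggplot2 figures for the main result types.

#' Plot fluorescence traces
#'
#' @param traces Trace tibble `(time_s, roi_id, channel, value)`.
#' @param protocol Optional [stim_protocol()]; stimulus trains are shaded.
#' @return A ggplot object (value vs time, colored by ROI, faceted by
#'   channel).
#' @export
plot_trace <- function(traces, protocol = NULL) {
  assert_trace_tbl(traces)
  p <- ggplot2::ggplot(traces, ggplot2::aes(.data$time_s, .data$value,
    colour = .data$roi_id
  ))
  if (!is.null(protocol)) {
    trains <- protocol_trains(protocol)
    p <- p + ggplot2::geom_rect(
      data = trains,
      ggplot2::aes(xmin = .data$t_start, xmax = .data$t_end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40",
      inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (s)", y = "fluorescence") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-round endocytic block with the arrest threshold
#'
#' @param object An `endurance_analysis` from [analyze_endurance()].
#' @param ... Unused.
#' @return A ggplot object: EB (%) vs round per neuron, with the block
#'   threshold as a dashed line.
#' @method autoplot endurance_analysis
#' @export
autoplot.endurance_analysis <- function(object, ...) {
  ggplot2::ggplot(
    object$per_round,
    ggplot2::aes(.data$round_index, .data$eb_percent, group = .data$neuron_id)
  ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_hline(
      yintercept = object$threshold,
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      x = "stimulus round", y = "endocytic block (%)",
      title = sprintf("Synaptic endurance (block at EB > %g%%)", object$threshold)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the glycogen-GS relation with binned means
#'
#' @param object A `gs_relation` from [glycogen_gs_relation()].
#' @param ... Unused.
#' @return A ggplot object: per-cell scatter, OLS line, binned mean +/- SEM.
#' @method autoplot gs_relation
#' @export
autoplot.gs_relation <- function(object, ...) {
  co <- coef(object$model)
  ggplot2::ggplot(
    object$records,
    ggplot2::aes(.data[[object$gs]], .data[[object$glycogen]])
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_abline(
      intercept = co[1], slope = co[2],
      linetype = "dashed"
    ) +
    ggplot2::geom_pointrange(
      data = object$bins,
      ggplot2::aes(
        x = .data$gs_bin_mid, y = .data$glycogen_mean,
        ymin = .data$glycogen_mean - .data$glycogen_sem,
        ymax = .data$glycogen_mean + .data$glycogen_sem
      ),
      colour = "red", inherit.aes = FALSE
    ) +
    ggplot2::labs(
      x = "normalized GS intensity", y = "normalized glycogen intensity"
    ) +
    ggplot2::theme_minimal()
}

#' Plot ATP phase decomposition per group
#'
#' @param phases Tibble of [atp_phases()] rows with a grouping column.
#' @param group Name of the grouping column (default `"arm"`).
#' @return A ggplot object: baseline/drop/recovery per group.
#' @export
plot_atp_phases <- function(phases, group = "arm") {
  long <- tidyr::pivot_longer(
    phases,
    c("baseline_percent", "drop_percent", "recovery_percent"),
    names_to = "phase", values_to = "percent"
  )
  long$phase <- factor(long$phase,
    levels = c("baseline_percent", "drop_percent", "recovery_percent"),
    labels = c("baseline", "drop", "recovery")
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$phase, .data$percent,
    colour = .data[[group]]
  )) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::labs(x = NULL, y = "% of baseline") +
    ggplot2::theme_minimal()
}
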