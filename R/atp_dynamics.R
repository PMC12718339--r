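#' Ratiometric ATP trace from sensor and reference channels
#'
#' Divides the ATP-sensor channel by the expression-reference channel,
#' frame-wise per ROI. Frames where the reference falls below a floor —
#' by default three times its estimated noise sd — are masked (`NA`) and
#' reported, never silently ratioed against a near-zero denominator.
#' Any gain or multiplicative bleaching shared by both channels cancels.
#'
#' @param traces Trace tibble `(time_s, roi_id, channel, value)` containing
#'   both channels on a shared time axis per ROI.
#' @param sensor,reference Channel labels (defaults `"sensor"`,
#'   `"reference"`).
#' @param reference_floor Absolute floor for the reference channel; when
#'   `NULL`, estimated per ROI as `3 * sd(diff(reference)) / sqrt(2)`.
#' @return A trace tibble with `channel = "ratio"`, masked frames as `NA`,
#'   and attribute `"n_masked"`.
#' @export
compute_ratio <- function(traces, sensor = "sensor", reference = "reference",
                          reference_floor = NULL) {
  assert_trace_tbl(traces)
  wide <- traces |>
    dplyr::filter(.data$channel %in% c(sensor, reference)) |>
    tidyr::pivot_wider(names_from = "channel", values_from = "value")
  if (!all(c(sensor, reference) %in% names(wide))) {
    abort(sprintf("Traces must contain both channels '%s' and '%s'.", sensor, reference))
  }
  out <- wide |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(function(df, key) {
      ref <- df[[reference]]
      floor_i <- reference_floor %||% (3 * sd(diff(ref)) / sqrt(2))
      ok <- is.finite(ref) & ref > floor_i
      df$value <- ifelse(ok, df[[sensor]] / ref, NA_real_)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(channel = "ratio") |>
    dplyr::select("time_s", "roi_id", "channel", "value")
  n_masked <- sum(!is.finite(out$value))
  if (n_masked == nrow(out)) {
    abort("All frames masked: the reference channel never exceeds its floor.")
  }
  attr(out, "n_masked") <- n_masked
  out
}

#' Average ROI ratios into a baseline-normalized neuron trace
#'
#' The per-neuron ATP signal: the mean across all ROI ratio traces per frame,
#' normalized to its own pre-stimulation baseline and expressed in percent
#' (baseline = 100%).
#'
#' @param ratios Ratio trace tibble from [compute_ratio()] (one neuron's
#'   ROIs).
#' @param protocol A [stim_protocol()]; the baseline window is the
#'   `baseline_window` seconds immediately before the first stimulus train
#'   (reference round excluded).
#' @param baseline_window Seconds of baseline (default 60).
#' @return Tibble `(time_s, value)` with `value` in percent of baseline.
#' @export
neuron_average_and_baseline <- function(ratios, protocol, baseline_window = 60) {
  assert_trace_tbl(ratios)
  onset <- stim_onset(protocol)
  avg <- ratios |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop")
  base_idx <- avg$time_s < onset & avg$time_s >= onset - baseline_window
  if (!any(base_idx)) abort("Empty baseline window before stimulation.")
  base <- mean(avg$value[base_idx], na.rm = TRUE)
  if (!is.finite(base) || base <= 0) abort("Baseline level is not positive.")
  avg$value <- 100 * avg$value / base
  avg
}

#' Decompose an ATP trace into baseline, drop and recovery phases
#'
#' Phase read-outs of a baseline-normalized neuron trace around a long
#' stimulus train: the baseline is 100% by construction; the drop is
#' `100 - min` of the trace within the train window (plus a short grace
#' period, where the minimum typically falls near train end); the recovery
#' is the mean over the final `recovery_window` seconds of the recording.
#'
#' @param neuron_trace Tibble `(time_s, value)` from
#'   [neuron_average_and_baseline()].
#' @param protocol A [stim_protocol()] declaring a `long_train` (or rounds,
#'   in which case the full stimulation period is used).
#' @param drop_grace Seconds after train end still searched for the minimum
#'   (default 10).
#' @param recovery_window Final seconds averaged for the recovery level
#'   (default 60).
#' @param drop_mode `"min"` (default: minimum within the window) or
#'   `"end"` (value at train end).
#' @return One-row tibble: `baseline_percent` (100), `drop_percent`,
#'   `recovery_percent`, `t_min`, and the window definitions used.
#' @export
atp_phases <- function(neuron_trace, protocol, drop_grace = 10,
                       recovery_window = 60, drop_mode = c("min", "end")) {
  drop_mode <- match.arg(drop_mode)
  if (!all(c("time_s", "value") %in% names(neuron_trace))) {
    abort("`neuron_trace` needs columns time_s and value.")
  }
  trains <- protocol_trains(protocol)
  stim <- trains[trains$label != "reference", ]
  if (!nrow(stim)) abort("Protocol declares no stimulation for phase analysis.")
  w0 <- min(stim$t_start)
  w1 <- max(stim$t_end) + drop_grace
  tmax <- max(neuron_trace$time_s)
  if (w1 > tmax || max(stim$t_end) + recovery_window > tmax) {
    abort("Stimulation or recovery window lies outside the trace.")
  }
  win <- neuron_trace[neuron_trace$time_s >= w0 & neuron_trace$time_s <= w1, ]
  if (drop_mode == "min") {
    i <- which.min(win$value)
  } else {
    i <- which.min(abs(win$time_s - max(stim$t_end)))
  }
  tail_tr <- neuron_trace[neuron_trace$time_s >= tmax - recovery_window, ]
  tibble(
    baseline_percent = 100,
    drop_percent = 100 - win$value[i],
    recovery_percent = mean(tail_tr$value, na.rm = TRUE),
    t_min = win$time_s[i],
    drop_window_start = w0,
    drop_window_end = w1,
    recovery_window = recovery_window,
    drop_mode = drop_mode
  )
}
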