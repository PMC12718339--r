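#' Normalize a pHluorin trace to the total sensor pool
#'
#' Converts raw fluorescence to percent of total sensor fluorescence by
#' subtracting the pre-stimulation level and dividing by the NH4Cl-revealed
#' total: `100 * (F - F0) / (F_NH4Cl - F0)`. `F0` is the mean over the
#' pre-stimulus window; `F_NH4Cl` is a robust plateau level (median of the
#' central 60% of the epoch, which ignores perfusion transients at the
#' epoch edges).
#'
#' @param trace Trace tibble `(time_s, roi_id, channel, value)`; may contain
#'   several ROIs, each normalized independently.
#' @param protocol A [stim_protocol()] declaring an `nh4cl_epoch` inside the
#'   trace span.
#' @return The trace tibble with `value` in percent of total pool.
#' @export
normalize_to_total_pool <- function(trace, protocol) {
  assert_trace_tbl(trace)
  ep <- protocol$nh4cl_epoch
  if (is.null(ep)) abort("Protocol declares no NH4Cl epoch.")
  span <- range(trace$time_s)
  if (ep[1] < span[1] || ep[2] > span[2]) {
    abort("The NH4Cl epoch lies outside the trace span.")
  }
  t0 <- stim_onset(protocol, include_reference = TRUE)
  pad <- 0.2 * (ep[2] - ep[1])
  trace |>
    dplyr::group_by(.data$roi_id, .data$channel) |>
    dplyr::group_modify(function(df, key) {
      f0 <- mean(df$value[df$time_s < t0])
      plateau <- median(df$value[df$time_s >= ep[1] + pad & df$time_s <= ep[2] - pad])
      if (!is.finite(f0) || !is.finite(plateau)) {
        abort(sprintf("Cannot normalize ROI %s: empty baseline or NH4Cl window.", key$roi_id))
      }
      if (plateau <= f0) {
        abort(sprintf(
          "NH4Cl calibration failure for ROI %s: plateau (%.3g) does not exceed baseline (%.3g).",
          key$roi_id, plateau, f0
        ))
      }
      df$value <- 100 * (df$value - f0) / (plateau - f0)
      df
    }) |>
    dplyr::ungroup() |>
    dplyr::select("time_s", "roi_id", "channel", "value")
}

#' Normalize a round segment to its stimulus peak
#'
#' Rescales a single-round trace segment so the pre-round baseline maps to 0
#' and the stimulus peak to 1: `(F - baseline_pre) / (peak - baseline_pre)`.
#' Used for single-train displays; the endocytic-block statistic is invariant
#' to this (or any other affine) rescaling.
#'
#' @param segment Tibble with `time_s` and `value` covering one stimulus
#'   round.
#' @param baseline_pre Baseline level; defaults to the first value.
#' @return The segment with `value` rescaled (peak = 1).
#' @export
normalize_to_peak <- function(segment, baseline_pre = NULL) {
  if (!all(c("time_s", "value") %in% names(segment))) {
    abort("`segment` needs columns time_s and value.")
  }
  baseline_pre <- baseline_pre %||% segment$value[1]
  peak <- max(segment$value)
  if (peak <= baseline_pre) {
    abort("Non-responding segment: peak does not exceed the pre-round baseline.")
  }
  segment$value <- (segment$value - baseline_pre) / (peak - baseline_pre)
  segment
}

#' Segment a trace into per-round stimulus responses
#'
#' Cuts one response record per main stimulus round: the peak is the maximum
#' within `[t_stim_start, t_stim_end + peak_grace]`, and the pre-round
#' baseline is the mean over the final `baseline_window` seconds of quiet
#' before the round.
#'
#' @param trace Single-ROI trace tibble (columns `time_s`, `value`; a
#'   `roi_id` column must be constant if present).
#' @param protocol A [stim_protocol()] whose rounds lie within the trace.
#' @param peak_grace Seconds after stimulus end still searched for the peak.
#' @param baseline_window Seconds of pre-round baseline.
#' @return A tibble with one row per round: `round_index`, `t_stim_start`,
#'   `t_stim_end`, `baseline_pre`, `t_peak`, `peak_value`.
#' @export
segment_rounds <- function(trace, protocol, peak_grace = 2, baseline_window = 5) {
  if (!all(c("time_s", "value") %in% names(trace))) {
    abort("`trace` needs columns time_s and value.")
  }
  if ("roi_id" %in% names(trace) && dplyr::n_distinct(trace$roi_id) > 1) {
    abort("`segment_rounds()` expects a single ROI; group or split first.")
  }
  trains <- protocol_trains(protocol)
  rounds <- trains[trains$label == "round", ]
  if (!nrow(rounds)) abort("Protocol declares no main stimulus rounds.")
  span <- range(trace$time_s)
  if (min(rounds$t_start) < span[1] || max(rounds$t_end) > span[2]) {
    abort("Protocol rounds lie outside the trace span.")
  }
  purrr::map(seq_len(nrow(rounds)), function(k) {
    t0 <- rounds$t_start[k]
    t1 <- rounds$t_end[k]
    base_idx <- trace$time_s < t0 & trace$time_s >= t0 - baseline_window
    win_idx <- trace$time_s >= t0 & trace$time_s <= t1 + peak_grace
    if (!any(base_idx) || !any(win_idx)) {
      abort(sprintf("Round %d has an empty baseline or stimulus window.", k))
    }
    v <- trace$value[win_idx]
    tt <- trace$time_s[win_idx]
    i_peak <- which.max(v)
    tibble(
      round_index = rounds$round_index[k],
      t_stim_start = t0, t_stim_end = t1,
      baseline_pre = mean(trace$value[base_idx]),
      t_peak = tt[i_peak], peak_value = v[i_peak]
    )
  }) |> purrr::list_rbind()
}

#' Fit the post-stimulus decay time constant
#'
#' Least-squares fit of `F(t) = A * exp(-(t - t_peak) / tau) + C` to the
#' post-peak portion of a round segment. The time constant of the reference
#' round in 5 mM glucose (`tau`) defines the 3-tau probe time of the
#' endocytic-block statistic.
#'
#' @param segment Tibble with `time_s` and `value`; the fit starts at the
#'   segment's maximum.
#' @param min_points Minimum number of post-peak samples required.
#' @return One-row tibble: `tau` (s), `A`, `C`, `resid_norm` (residual RMS),
#'   `converged`, `n_points`.
#' @export
fit_decay_tau <- function(segment, min_points = 8) {
  if (!all(c("time_s", "value") %in% names(segment))) {
    abort("`segment` needs columns time_s and value.")
  }
  i_peak <- which.max(segment$value)
  post <- segment[seq(i_peak, nrow(segment)), ]
  if (nrow(post) < min_points) {
    abort(sprintf("Too few post-peak samples (%d < %d) for a decay fit.", nrow(post), min_points))
  }
  amp <- max(post$value) - min(post$value)
  if (!is.finite(amp) || amp <= 0 || amp < 1e-9 * max(abs(post$value), 1e-12)) {
    abort("Flat segment: no decay to fit.")
  }
  t <- post$time_s - post$time_s[1]
  v <- post$value

  # log-linear starting values
  c0 <- min(v) - 0.05 * amp
  lv <- log(pmax(v - c0, amp * 1e-3))
  sl <- coef(lm(lv ~ t))[2]
  tau0 <- if (is.finite(sl) && sl < 0) min(max(-1 / sl, 1e-3), 10 * max(t)) else max(t) / 3

  span <- max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ C + A * exp(-t / tau),
      start = list(C = c0, A = v[1] - c0, tau = tau0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) abort(sprintf("Decay fit failed to converge: %s", conditionMessage(e)))
  )
  est <- coef(fit)
  info <- fit$convInfo
  if (!is.finite(est[["tau"]]) || est[["tau"]] <= span * 2e-4 || est[["tau"]] >= span * 50) {
    abort(sprintf(
      "Decay fit returned an implausible tau (%.3g s over a %.3g s segment); residual RMS %.3g.",
      est[["tau"]], span, sqrt(mean(stats::residuals(fit)^2))
    ))
  }
  tibble(
    tau = est[["tau"]], A = est[["A"]], C = est[["C"]],
    resid_norm = sqrt(mean(stats::residuals(fit)^2)),
    converged = isTRUE(info$isConv),
    n_points = nrow(post)
  )
}

#' Endocytic block (EB) of a stimulus round
#'
#' The EB statistic is the percentage of the exocytic signal remaining a
#' defined time after the stimulus: the trace is probed at
#' `t_peak + 3 * tau_ref` (three reference decay constants), and
#' `EB = 100 * (F_probe - baseline_pre) / (peak - baseline_pre)`. A perfect
#' single-exponential retrieval gives `EB = 100 * exp(-3)`, about 5%; a
#' complete arrest of endocytosis gives 100%. The probe value is a local
#' average over `2 * probe_halfwidth + 1` frames to avoid single-frame noise.
#' Values above 100 (a post-stimulus rise) clamp to 100 with a warning;
#' values below 0 clamp to 0.
#'
#' @param trace Single-ROI trace tibble (`time_s`, `value`).
#' @param rounds Round table from [segment_rounds()].
#' @param tau_ref Reference decay constant in seconds (> 0), fitted in 5 mM
#'   glucose via [fit_decay_tau()].
#' @param probe_halfwidth Frames on each side of the probe time included in
#'   the local average (default 2).
#' @return `rounds` with an `eb_percent` column appended.
#' @export
compute_eb <- function(trace, rounds, tau_ref, probe_halfwidth = 2) {
  check_number(tau_ref, "tau_ref", min = 0, strict_min = TRUE)
  dt <- median(diff(sort(unique(trace$time_s))))
  eb <- vapply(seq_len(nrow(rounds)), function(k) {
    probe_t <- rounds$t_peak[k] + 3 * tau_ref
    if (probe_t > max(trace$time_s)) {
      abort(sprintf(
        "EB probe time %.1f s (round %d) lies beyond the trace end (%.1f s).",
        probe_t, rounds$round_index[k], max(trace$time_s)
      ))
    }
    w <- abs(trace$time_s - probe_t) <= (probe_halfwidth + 0.5) * dt
    probe <- mean(trace$value[w])
    amp <- rounds$peak_value[k] - rounds$baseline_pre[k]
    if (amp <= 0) {
      abort(sprintf("Round %d has a non-positive exocytic amplitude.", rounds$round_index[k]))
    }
    100 * (probe - rounds$baseline_pre[k]) / amp
  }, numeric(1))
  if (any(eb > 100 + 1e-9)) {
    warn(sprintf(
      "EB above 100%% in round(s) %s (post-stimulus rise); clamped to 100.",
      paste(rounds$round_index[eb > 100 + 1e-9], collapse = ", ")
    ))
  }
  rounds$eb_percent <- pmin(100, pmax(0, eb))
  rounds
}

#' Rounds of stimulation until endocytic block
#'
#' The synaptic-endurance readout: the first stimulus round whose EB exceeds
#' `threshold` (strictly). Neurons that never cross within `max_rounds`
#' rounds are censored and assigned `rounds_to_block = max_rounds`, so that
#' censored neurons still contribute the observation horizon to group means.
#'
#' @param eb_series Ordered numeric vector of per-round EB percentages (all
#'   in `[0, 100]`).
#' @param threshold EB threshold in percent (default 50).
#' @param max_rounds Censoring horizon (default 30 rounds).
#' @return One-row tibble: `rounds_to_block`, `censored`, `threshold`,
#'   `max_rounds`, `n_rounds` (length of the series).
#' @export
endurance_rounds <- function(eb_series, threshold = 50, max_rounds = 30) {
  if (!length(eb_series)) abort("`eb_series` is empty.")
  if (length(eb_series) > max_rounds) {
    abort("`eb_series` is longer than `max_rounds`.")
  }
  if (any(!is.finite(eb_series)) || any(eb_series < 0 | eb_series > 100)) {
    abort("EB values must lie in [0, 100] after clamping; got values outside.")
  }
  hit <- which(eb_series > threshold)
  tibble(
    rounds_to_block = if (length(hit)) hit[1] else as.integer(max_rounds),
    censored = !length(hit),
    threshold = threshold,
    max_rounds = as.integer(max_rounds),
    n_rounds = length(eb_series)
  )
}

#' Full synaptic-endurance analysis of pHluorin traces
#'
#' Runs the complete endurance pipeline per neuron: total-pool normalization
#' (when the protocol declares an NH4Cl epoch), reference-round decay fit for
#' `tau_ref`, per-round segmentation, EB computation at `3 * tau_ref`, and
#' the rounds-to-block statistic with censoring.
#'
#' @param traces Trace tibble `(time_s, roi_id, channel, value)`; each
#'   `roi_id` is treated as one neuron.
#' @param protocol A [stim_protocol()]; needs a `reference_round_start`
#'   unless `tau_ref` is supplied.
#' @param eb_threshold EB threshold in percent (default 50).
#' @param max_rounds Censoring horizon; defaults to the protocol's round
#'   count.
#' @param tau_ref Optional fixed reference decay constant (s); fitted per
#'   neuron from the reference round when `NULL`.
#' @param tau_fit_window Seconds after the reference-train end used for the
#'   decay fit.
#' @return An object of class `endurance_analysis`: list with `per_neuron`
#'   (one row per neuron: `neuron_id`, `tau_ref`, `rounds_to_block`,
#'   `censored`), `per_round` (per-round peaks and EB), `threshold`,
#'   `max_rounds`. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @export
analyze_endurance <- function(traces, protocol,
                              eb_threshold = 50,
                              max_rounds = protocol$rounds,
                              tau_ref = NULL,
                              tau_fit_window = 40) {
  assert_trace_tbl(traces)
  if (is.null(tau_ref) && is.null(protocol$reference_round_start)) {
    abort("Protocol has no reference round; supply `tau_ref` explicitly.")
  }
  trains <- protocol_trains(protocol)
  ref <- trains[trains$label == "reference", ]

  res <- traces |>
    dplyr::group_by(neuron_id = .data$roi_id) |>
    dplyr::group_map(function(df, key) {
      tr <- if (!is.null(protocol$nh4cl_epoch)) {
        df$roi_id <- key$neuron_id
        normalize_to_total_pool(df, protocol)
      } else {
        df
      }
      tau_i <- tau_ref
      if (is.null(tau_i)) {
        seg <- tr[tr$time_s >= ref$t_start & tr$time_s <= ref$t_end + tau_fit_window, ]
        tau_i <- fit_decay_tau(seg)$tau
      }
      rounds <- segment_rounds(tr, protocol) |>
        compute_eb(trace = tr, tau_ref = tau_i)
      endur <- endurance_rounds(rounds$eb_percent, eb_threshold, max_rounds)
      list(
        per_neuron = tibble(
          neuron_id = key$neuron_id, tau_ref = tau_i,
          rounds_to_block = endur$rounds_to_block, censored = endur$censored
        ),
        per_round = dplyr::mutate(rounds, neuron_id = key$neuron_id, .before = 1)
      )
    })

  structure(
    list(
      per_neuron = purrr::list_rbind(purrr::map(res, "per_neuron")),
      per_round = purrr::list_rbind(purrr::map(res, "per_round")),
      threshold = eb_threshold,
      max_rounds = as.integer(max_rounds)
    ),
    class = "endurance_analysis"
  )
}

#' @export
print.endurance_analysis <- function(x, ...) {
  g <- glance(x)
  cat("<endurance_analysis>\n")
  cat(sprintf(
    "  %d neuron(s); rounds to block (EB > %g%%): %s; %d censored at %d rounds\n",
    g$n_neurons, x$threshold, g$label, g$n_censored, x$max_rounds
  ))
  invisible(x)
}
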