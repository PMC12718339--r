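#' Simulate a per-neuron pHluorin trace
#'
#' Builds a synthetic synaptophysin-pHluorin fluorescence trace over a
#' stimulation protocol. Each stimulus train exocytoses a fixed fraction of
#' the still-releasable vesicle pool (a stimulus-locked rise); after the
#' train, only the endocytic-capacity fraction of the exocytosed signal is
#' retrieved, decaying exponentially with `endocytosis_tau`, while the
#' remainder stays stranded on the surface — so retrieval failures compound
#' across rounds. Capacity per round is the Hill-mapped mean ATP over the
#' retrieval window of the accompanying [simulate_terminal_state()]
#' trajectory. An NH4Cl epoch, when the protocol declares one, unquenches the
#' whole pool and sets fluorescence to the total-sensor level used by
#' [normalize_to_total_pool()].
#'
#' Fluorescence is reported in arbitrary camera units
#' `offset + gain * (resting_surface + surface(t))`, photobleached at
#' `params$bleach_rate`, with additive Gaussian noise of sd
#' `params$noise_sd` times the first-round peak amplitude.
#'
#' @param params A [sim_params()] object.
#' @param protocol A [stim_protocol()]; must cover the same span as `state`.
#' @param state Optional precomputed [simulate_terminal_state()] trajectory;
#'   simulated from `(params, protocol, seed)` when `NULL`.
#' @param seed Integer seed; the same `(params, protocol, seed)` always
#'   yields a bit-identical trace.
#' @param neuron_id Identifier used in the `roi_id` column.
#' @param capacity_override Optional numeric vector of per-round endocytic
#'   capacities in `[0, 1]` (recycled to the number of main rounds),
#'   bypassing the ATP model.
#' @param force_arrest_round Optional integer: rounds before it get capacity
#'   1, rounds from it on get `arrest_capacity`. Used for ground-truth
#'   recovery experiments.
#' @param arrest_capacity Capacity assigned from `force_arrest_round` on.
#' @param gain,offset Camera gain and offset (arbitrary units).
#' @param resting_surface Fraction of the total pool resident on the surface
#'   at rest (sets the gap between baseline and the NH4Cl plateau).
#'
#' @return An object of class `ph_sim`: a list with
#'   * `trace` — tibble `(time_s, roi_id, channel = "ph", value)`;
#'   * `rounds` — per-round ground truth `(neuron_id, round_index, capacity,
#'     exo_frac, eb_true)` with `exo_frac` in total-pool units;
#'   * `truth` — one-row tibble with the parameters actually used (true tau,
#'     efficiency, true arrest round and censoring flag).
#' @export
simulate_ph_trace <- function(params, protocol,
                              state = NULL,
                              seed = NULL,
                              neuron_id = "neuron_1",
                              capacity_override = NULL,
                              force_arrest_round = NULL,
                              arrest_capacity = 0.1,
                              gain = 1000, offset = 100,
                              resting_surface = 0.08) {
  stopifnot(inherits(params, "sim_params"), inherits(protocol, "stim_protocol"))
  if (is.null(state)) {
    state <- simulate_terminal_state(params, protocol, seed = seed)
  }
  if (max(state$time_s) < protocol$span_s - protocol$frame_interval / 2) {
    abort("`state` does not cover the protocol span.")
  }
  trains <- protocol_trains(protocol)
  time_s <- state$time_s
  n <- length(time_s)
  q <- resting_surface

  # per-train endocytic capacity
  caps <- vapply(seq_len(nrow(trains)), function(k) {
    round_capacity(state, trains$t_end[k], params)
  }, numeric(1))
  main <- which(trains$label == "round")
  if (!is.null(capacity_override)) {
    ov <- rep_len(capacity_override, length(main))
    if (any(ov < 0 | ov > 1)) abort("`capacity_override` values must lie in [0, 1].")
    caps[main] <- ov
  } else if (!is.null(force_arrest_round)) {
    r <- trains$round_index[main]
    caps[main] <- ifelse(r >= force_arrest_round, arrest_capacity, 1)
    caps[trains$label == "reference"] <- 1
  }

  surface <- numeric(n) # exocytosed, not-yet-retrieved signal (total-pool units)
  stranded <- 0
  exo <- numeric(nrow(trains))
  for (k in seq_len(nrow(trains))) {
    frac <- 1 - (1 - params$exo_pool_fraction_per_round)^(trains$n_aps[k] / 50)
    e_k <- frac * max(0, 1 - q - stranded)
    exo[k] <- e_k
    t0 <- trains$t_start[k]
    t1 <- trains$t_end[k]
    rising <- time_s >= t0 & time_s < t1
    surface[rising] <- surface[rising] + e_k * (time_s[rising] - t0) / (t1 - t0)
    after <- time_s >= t1
    surface[after] <- surface[after] +
      e_k * ((1 - caps[k]) + caps[k] * exp(-(time_s[after] - t1) / params$endocytosis_tau))
    stranded <- stranded + e_k * (1 - caps[k])
  }

  value <- (offset + gain * (q + surface)) * exp(-params$bleach_rate * time_s)
  if (!is.null(protocol$nh4cl_epoch)) {
    ep <- protocol$nh4cl_epoch
    in_ep <- time_s >= ep[1] & time_s <= ep[2]
    value[in_ep] <- (offset + gain * 1) * exp(-params$bleach_rate * time_s[in_ep])
  }
  if (params$noise_sd > 0) {
    peak_amp <- gain * params$exo_pool_fraction_per_round * (1 - q)
    value <- value + with_seed(
      derive_seed(seed %||% 0, 202),
      rnorm(n, 0, params$noise_sd * peak_amp)
    )
  }

  trace <- tibble(
    time_s = time_s, roi_id = neuron_id, channel = "ph", value = value
  )

  pool_scale <- 1 - q # converts surface units to pool-fraction units
  rounds <- tibble(
    neuron_id = neuron_id,
    round_index = trains$round_index[main],
    capacity = caps[main],
    exo_frac = exo[main] / pool_scale,
    eb_true = 100 * ((1 - caps[main]) + caps[main] * exp(-3))
  )
  arrest <- which(rounds$eb_true > 50)
  truth <- tibble(
    neuron_id = neuron_id,
    seed = seed %||% NA_integer_,
    efficiency = attr(state, "efficiency") %||% NA_real_,
    tau_true = params$endocytosis_tau,
    arrest_round_true = if (length(arrest)) arrest[1] else length(main),
    censored_true = !length(arrest),
    n_rounds = length(main)
  )
  structure(list(trace = trace, rounds = rounds, truth = truth), class = "ph_sim")
}

#' Simulate a cohort of pHluorin neurons for a named condition
#'
#' Convenience wrapper running [simulate_terminal_state()] and
#' [simulate_ph_trace()] for `n_neurons` independent neurons of one
#' experimental condition, with per-neuron seeds derived from `seed`.
#'
#' @param condition A preset name (see [condition_presets()]) or a
#'   [sim_params()] object.
#' @param n_neurons Number of neurons.
#' @param seed Integer master seed.
#' @param protocol A [stim_protocol()]; defaults to [endurance_protocol()]
#'   at the preset's glucose level.
#' @param ... Passed on to [simulate_ph_trace()].
#' @return A `ph_sim` with the neurons' traces, per-round truth and
#'   per-neuron truth row-bound; `roi_id`/`neuron_id` are
#'   `"<condition>_<i>"`.
#' @export
simulate_ph_neurons <- function(condition, n_neurons = 10, seed = 1,
                                protocol = NULL, ...) {
  params <- if (inherits(condition, "sim_params")) condition else condition_presets(condition)
  label <- if (is.character(condition)) condition else "custom"
  if (is.null(protocol)) {
    protocol <- endurance_protocol(glucose_mM = params$glucose_mM)
  }
  sims <- purrr::map(seq_len(n_neurons), function(i) {
    simulate_ph_trace(
      params, protocol,
      seed = derive_seed(seed, i),
      neuron_id = sprintf("%s_%02d", label, i),
      ...
    )
  })
  structure(
    list(
      trace = purrr::list_rbind(purrr::map(sims, "trace")),
      rounds = purrr::list_rbind(purrr::map(sims, "rounds")),
      truth = purrr::list_rbind(purrr::map(sims, "truth"))
    ),
    class = "ph_sim"
  )
}
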