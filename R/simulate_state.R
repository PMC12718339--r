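#' Simulate nerve-terminal ATP and glycogen dynamics
#'
#' Integrates the bioenergetic model of [sim_params()] over a stimulation
#' protocol with a forward-Euler step equal to the frame interval. The state
#' is the relative cytosolic ATP level, the glycogen store, and the vesicle
#' pool awaiting retrieval; all three stay in `[0, 1]`.
#'
#' The trajectory is fully deterministic given `(params, protocol, seed)`:
#' the only random draw is the per-neuron metabolic-efficiency factor
#' (lognormal, sdlog `params$neuron_cv`), which can instead be fixed through
#' `efficiency`.
#'
#' @param params A [sim_params()] object.
#' @param protocol A [stim_protocol()].
#' @param seed Integer seed for the per-neuron efficiency draw, or `NULL`
#'   (efficiency 1).
#' @param efficiency Optional explicit efficiency factor (> 0); overrides the
#'   seeded draw.
#' @return A tibble with columns `time_s`, `atp`, `glycogen`, `pending_pool`
#'   (surface-stranded vesicle pool), sampled at the protocol's frame
#'   interval, with the efficiency factor attached as attribute
#'   `"efficiency"`.
#' @export
simulate_terminal_state <- function(params, protocol, seed = NULL, efficiency = NULL) {
  stopifnot(inherits(params, "sim_params"), inherits(protocol, "stim_protocol"))
  if (is.null(efficiency)) {
    efficiency <- if (is.null(seed)) 1 else {
      with_seed(derive_seed(seed, 101), exp(rnorm(1, 0, params$neuron_cv)))
    }
  }
  check_number(efficiency, "efficiency", min = 0, strict_min = TRUE)

  dt <- protocol$frame_interval
  time_s <- seq(0, protocol$span_s, by = dt)
  n <- length(time_s)
  trains <- protocol_trains(protocol)
  glucose <- glucose_at(protocol, time_s)

  # Per-frame AP rate and exocytosis rate (fraction of available pool per s).
  ap_rate <- numeric(n)
  exo_gain <- numeric(n) # release rate coefficient applied to (1 - pending)
  f50 <- params$exo_pool_fraction_per_round
  for (k in seq_len(nrow(trains))) {
    idx <- time_s >= trains$t_start[k] & time_s < trains$t_end[k]
    ap_rate[idx] <- trains$frequency[k]
    dur <- trains$t_end[k] - trains$t_start[k]
    frac <- 1 - (1 - f50)^(trains$n_aps[k] / 50)
    exo_gain[idx] <- frac / dur
  }

  gpa <- params$glycogen_per_atp / efficiency
  atp <- 1
  glyc <- initial_store(params)
  pend <- 0
  out_atp <- out_glyc <- out_pend <- numeric(n)

  for (i in seq_len(n)) {
    out_atp[i] <- atp
    out_glyc[i] <- glyc
    out_pend[i] <- pend

    cap <- hill_capacity(atp, params$atp_capacity_halfpoint, params$hill_n)
    retrieval <- pend / params$endocytosis_tau
    demand <- params$atp_rest_cost +
      params$atp_cost_per_ap * ap_rate[i] +
      params$recycle_cost * retrieval
    # glycogenolysis engages when bath glucose is (near) absent
    s_gp <- if (glucose[i] < 0.5) params$gp_activity * params$gp_rate * glyc else 0
    supply <- params$glucose_uptake_gain * glucose[i] + s_gp
    drain <- demand * min(1, atp / params$consumption_knee)

    atp <- min(1, max(0, atp + dt * (supply - drain)))
    glyc <- max(0, glyc - dt * gpa * s_gp)
    pend <- max(0, min(1, pend + dt * (exo_gain[i] * (1 - pend) - retrieval * cap)))
  }

  out <- tibble(time_s = time_s, atp = out_atp, glycogen = out_glyc, pending_pool = out_pend)
  attr(out, "efficiency") <- efficiency
  out
}

# Mean ATP over the retrieval window following a train, mapped through the
# Hill curve: the fraction of this round's exocytosed signal that will be
# retrieved.
round_capacity <- function(state, t_end, params) {
  w <- state$time_s >= t_end & state$time_s <= t_end + 3 * params$endocytosis_tau
  if (!any(w)) abort("State trajectory does not cover the retrieval window.")
  hill_capacity(mean(state$atp[w]), params$atp_capacity_halfpoint, params$hill_n)
}
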