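# Fixtures built in code, shared across test files.

# A clean single-exponential decay trace: instantaneous rise to `peak` at
# t_peak, then decay back toward `baseline` with time constant `tau`.
make_exponential_trace <- function(tau = 8, peak = 100, baseline = 0,
                                   t_peak = 10, t_end = 80, dt = 0.5,
                                   roi_id = "roi_1") {
  tt <- seq(0, t_end, by = dt)
  v <- ifelse(tt < t_peak, baseline,
    baseline + (peak - baseline) * exp(-(tt - t_peak) / tau)
  )
  tibble::tibble(time_s = tt, roi_id = roi_id, channel = "ph", value = v)
}

# Noise-free simulation parameters (closed-form generator outputs).
noise_free_params <- function(...) {
  defaults <- list(noise_sd = 0, bleach_rate = 0, neuron_cv = 0)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

# Compact few-round protocol for fast unit tests. `reference = FALSE` drops
# the 5 mM reference round so capacity_override covers every train (no
# surface stranding outside the overridden rounds).
short_protocol <- function(rounds = 3, glucose_mM = 5, reference = TRUE) {
  last_end <- 120 + (rounds - 1) * 60 + 5
  stim_protocol(
    rounds = rounds, rounds_start = 120,
    reference_round_start = if (reference) 20,
    glucose_timeline = tibble::tibble(start_s = 0, glucose_mM = glucose_mM),
    nh4cl_epoch = c(last_end + 30, last_end + 60),
    span_s = last_end + 70
  )
}

# Brute-force oracle for the two-sample rank test: enumerate every split of
# the pooled values (not ranks) and count splits with a pairwise-count U at
# least as extreme as observed.
permutation_mw_p <- function(x, y, alternative = "two.sided") {
  pairwise_u <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- pairwise_u(x, y)
  splits <- utils::combn(length(pooled), n1)
  u_all <- apply(splits, 2, function(idx) pairwise_u(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  p_le <- mean(u_all <= u_obs + eps)
  p_ge <- mean(u_all >= u_obs - eps)
  switch(alternative,
    two.sided = min(1, 2 * min(p_le, p_ge)),
    less = p_le,
    greater = p_ge
  )
}

# Exposes the package's deterministic seed fan-out to tests.
derive_seed_for_test <- function(...) synendure:::derive_seed(...)
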