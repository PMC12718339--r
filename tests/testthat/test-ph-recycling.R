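test_that("total-pool normalization follows the stated arithmetic", {
  # F0 = 10, NH4Cl plateau = 110, peak = 30 -> peak maps to 20% of pool
  proto <- short_protocol(rounds = 1, reference = FALSE)
  ep <- proto$nh4cl_epoch
  tt <- seq(0, proto$span_s, by = 0.5)
  v <- rep(10, length(tt))
  v[tt >= 120 & tt < 125] <- 30
  v[tt >= ep[1] & tt <= ep[2]] <- 110
  tr <- tibble::tibble(time_s = tt, roi_id = "r1", channel = "ph", value = v)
  norm <- normalize_to_total_pool(tr, proto)
  expect_equal(max(norm$value[norm$time_s < ep[1]]), 20)
  expect_equal(norm$value[norm$time_s < 120][1], 0)

  # a trace identically F0 outside the epoch normalizes to identically 0
  v2 <- rep(10, length(tt))
  v2[tt >= ep[1] & tt <= ep[2]] <- 110
  tr2 <- tibble::tibble(time_s = tt, roi_id = "r1", channel = "ph", value = v2)
  norm2 <- normalize_to_total_pool(tr2, proto)
  expect_true(all(norm2$value[norm2$time_s < ep[1]] == 0))

  # calibration failure: plateau below baseline
  v3 <- rep(10, length(tt))
  v3[tt >= ep[1] & tt <= ep[2]] <- 5
  tr3 <- tibble::tibble(time_s = tt, roi_id = "r1", channel = "ph", value = v3)
  expect_error(normalize_to_total_pool(tr3, proto), "calibration failure")
})

test_that("peak normalization maps baseline to 0, peak to 1, and is affine-invariant", {
  seg <- tibble::tibble(
    time_s = 0:10,
    value = c(0, 1, 2, 3, 4, 5, 4, 3, 2.5, 2.2, 2)
  )
  norm <- normalize_to_peak(seg, baseline_pre = 0)
  expect_equal(max(norm$value), 1)
  expect_equal(norm$value[1], 0)
  # constructed ramp 0 -> 5 then decay to 2: tail maps to 0.4
  expect_equal(norm$value[11], 0.4)

  # any affine rescaling of the input yields the identical output
  seg2 <- seg
  seg2$value <- 7.3 * seg$value - 42
  norm2 <- normalize_to_peak(seg2, baseline_pre = -42)
  expect_equal(norm2$value, norm$value)

  # non-responding segment errors
  flat <- tibble::tibble(time_s = 0:10, value = rep(2, 11))
  expect_error(normalize_to_peak(flat), "Non-responding")
})

test_that("segment_rounds returns one response per declared round", {
  p <- noise_free_params()
  proto17 <- endurance_protocol(rounds = 17)
  sim <- simulate_ph_trace(p, proto17, seed = 1)
  segs <- segment_rounds(sim$trace, proto17)
  expect_equal(nrow(segs), 17)
  expect_equal(segs$round_index, 1:17)

  # single round: the peak is the constructed maximum
  proto1 <- short_protocol(rounds = 1, reference = FALSE)
  sim1 <- simulate_ph_trace(p, proto1, seed = 1, capacity_override = 1)
  seg1 <- segment_rounds(sim1$trace, proto1)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$peak_value, max(sim1$trace$value[sim1$trace$time_s < proto1$nh4cl_epoch[1]]))

  # noise off: per-round peak amplitudes equal the generator's exocytic steps
  proto3 <- short_protocol(rounds = 3, reference = FALSE)
  sim3 <- simulate_ph_trace(p, proto3, seed = 1, capacity_override = c(1, 0.5, 0.2))
  norm3 <- normalize_to_total_pool(sim3$trace, proto3)
  segs3 <- segment_rounds(norm3, proto3)
  amp <- segs3$peak_value - segs3$baseline_pre
  expect_equal(amp / 100, sim3$rounds$exo_frac, tolerance = 0.02)
})

test_that("decay fitting recovers a noiseless tau of 8 s and rejects flat input", {
  tr <- make_exponential_trace(tau = 8, peak = 100, baseline = 20, t_peak = 10)
  fit <- fit_decay_tau(tr)
  expect_equal(fit$tau, 8, tolerance = 1e-6)
  expect_equal(fit$C, 20, tolerance = 1e-4)
  expect_true(fit$converged)

  flat <- tibble::tibble(time_s = seq(0, 50, 0.5), value = rep(3, 101))
  expect_error(fit_decay_tau(flat), "Flat segment")
  expect_error(fit_decay_tau(tr[1:4, ]), "Too few")
})

test_that("median fitted tau stays within 10% of truth at 5% peak noise", {
  taus <- vapply(1:100, function(s) {
    set.seed(s)
    tr <- make_exponential_trace(tau = 8, peak = 100, baseline = 0, t_peak = 5, t_end = 60)
    tr$value <- tr$value + rnorm(nrow(tr), 0, 5)
    # fit from the true peak region on
    fit_decay_tau(tr[tr$time_s >= 5, ])$tau
  }, numeric(1))
  expect_lt(abs(median(taus) - 8) / 8, 0.10)
})

test_that("EB of a perfect exponential decay at 3 tau is about 5%", {
  tr <- make_exponential_trace(tau = 8, peak = 100, baseline = 0, t_peak = 130, t_end = 200)
  proto <- short_protocol(rounds = 1, reference = FALSE)
  rounds <- tibble::tibble(
    round_index = 1L, t_stim_start = 120, t_stim_end = 130,
    baseline_pre = 0, t_peak = 130, peak_value = 100
  )
  out <- compute_eb(tr, rounds, tau_ref = 8)
  expect_equal(out$eb_percent, 100 * exp(-3), tolerance = 0.01)

  # no decay after the peak -> EB = 100%
  tr_block <- tr
  tr_block$value[tr_block$time_s >= 130] <- 100
  expect_equal(compute_eb(tr_block, rounds, 8)$eb_percent, 100)

  # decay complete well before 3 tau -> EB ~ 0
  tr_fast <- make_exponential_trace(tau = 0.8, peak = 100, baseline = 0,
                                    t_peak = 130, t_end = 200)
  expect_lt(compute_eb(tr_fast, rounds, 8)$eb_percent, 0.5)

  # probe beyond the trace end errors
  expect_error(compute_eb(tr[tr$time_s <= 140, ], rounds, 8), "beyond the trace end")
})

test_that("EB is invariant under affine transforms of the raw trace", {
  p <- condition_presets("da_0gluc")
  proto <- short_protocol(rounds = 3, reference = FALSE, glucose_mM = 0)
  sim <- simulate_ph_trace(p, proto, seed = 9)
  tr <- sim$trace
  rounds <- segment_rounds(tr, proto)
  eb1 <- compute_eb(tr, rounds, tau_ref = 8)$eb_percent
  for (gain_offset in list(c(2.5, 100), c(0.3, -50), c(10, 0))) {
    tr2 <- tr
    tr2$value <- gain_offset[1] * tr$value + gain_offset[2]
    rounds2 <- segment_rounds(tr2, proto)
    eb2 <- compute_eb(tr2, rounds2, tau_ref = 8)$eb_percent
    expect_equal(eb2, eb1, tolerance = 1e-9)
  }
})

test_that("EB decreases as the simulator's ATP capacity rises", {
  p <- noise_free_params()
  proto <- short_protocol(rounds = 1, reference = FALSE)
  caps <- seq(0, 1, by = 0.1)
  ebs <- vapply(caps, function(cap) {
    sim <- simulate_ph_trace(p, proto, seed = 1, capacity_override = cap)
    rounds <- segment_rounds(sim$trace, proto)
    compute_eb(sim$trace, rounds, tau_ref = p$endocytosis_tau)$eb_percent
  }, numeric(1))
  expect_true(all(diff(ebs) < 0))
  expect_equal(ebs[1], 100, tolerance = 1e-6)
})

test_that("endurance_rounds applies the strict threshold and censoring rules", {
  r <- endurance_rounds(c(5, 6, 8, 20, 55, 60), threshold = 50, max_rounds = 30)
  expect_equal(r$rounds_to_block, 5)
  expect_false(r$censored)

  # 30 values all <= 50: censored at the horizon
  r2 <- endurance_rounds(rep(40, 30), threshold = 50, max_rounds = 30)
  expect_equal(r2$rounds_to_block, 30)
  expect_true(r2$censored)

  # first value above threshold blocks immediately
  expect_equal(endurance_rounds(c(60, 5, 5), max_rounds = 3)$rounds_to_block, 1)

  # threshold comparison is strict: exactly 50 does not block
  expect_true(endurance_rounds(rep(50, 5), max_rounds = 5)$censored)

  expect_error(endurance_rounds(numeric(0)), "empty")
  expect_error(endurance_rounds(c(5, 105)), "\\[0, 100\\]")
  expect_error(endurance_rounds(rep(10, 31), max_rounds = 30), "longer")
})

test_that("the full endurance pipeline recovers tau and forced arrest rounds", {
  p <- condition_presets("da_0gluc")
  proto <- endurance_protocol(rounds = 12)
  # noise off: tau recovered within 5%
  sim0 <- simulate_ph_trace(noise_free_params(), proto, seed = 1, force_arrest_round = 7)
  res0 <- analyze_endurance(sim0$trace, proto)
  expect_lt(abs(res0$per_neuron$tau_ref - 8) / 8, 0.05)
  expect_equal(res0$per_neuron$rounds_to_block, 7)
  expect_false(res0$per_neuron$censored)

  # default noise, several seeds: forced arrest recovered
  hits <- vapply(1:10, function(s) {
    sim <- simulate_ph_trace(p, proto, seed = s, force_arrest_round = 4 + s %% 6)
    res <- analyze_endurance(sim$trace, proto)
    res$per_neuron$rounds_to_block == 4 + s %% 6
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("tidy and glance summarize the endurance analysis", {
  proto <- endurance_protocol(rounds = 6, glucose_mM = 0)
  sim <- simulate_ph_neurons("da_gpi", n_neurons = 3, seed = 5, protocol = proto)
  res <- suppressWarnings(analyze_endurance(sim$trace, proto))
  td <- tidy(res)
  expect_equal(nrow(td), 18) # 3 neurons x 6 rounds
  gl <- glance(res)
  expect_equal(gl$n_neurons, 3)
  expect_match(gl$label, "±")
  expect_s3_class(autoplot(res), "ggplot")
})
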