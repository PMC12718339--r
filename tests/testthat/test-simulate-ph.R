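test_that("with full capacity and no noise each round decays to e^-3 at 3 tau", {
  p <- noise_free_params()
  proto <- short_protocol(rounds = 2, reference = FALSE)
  sim <- simulate_ph_trace(p, proto, seed = 1, capacity_override = c(1, 1))
  tr <- sim$trace
  rounds <- segment_rounds(tr, proto)
  for (k in 1:2) {
    probe_t <- rounds$t_peak[k] + 3 * p$endocytosis_tau
    probe <- tr$value[which.min(abs(tr$time_s - probe_t))]
    residual <- (probe - rounds$baseline_pre[k]) /
      (rounds$peak_value[k] - rounds$baseline_pre[k])
    expect_equal(residual, exp(-3), tolerance = 0.03)
  }
})

test_that("with zero capacity the post-round signal stays at its peak", {
  p <- noise_free_params()
  proto <- short_protocol(rounds = 1, reference = FALSE)
  sim <- simulate_ph_trace(p, proto, seed = 1, capacity_override = 0)
  tr <- sim$trace
  rounds <- segment_rounds(tr, proto)
  after <- tr$value[tr$time_s > rounds$t_peak & tr$time_s < rounds$t_peak + 30]
  expect_true(all(abs(after - rounds$peak_value) < 1e-9))
})

test_that("identical seeds give bit-identical traces; different seeds differ", {
  p <- condition_presets("da_0gluc")
  proto <- short_protocol(rounds = 2, glucose_mM = 0)
  a <- simulate_ph_trace(p, proto, seed = 42)
  b <- simulate_ph_trace(p, proto, seed = 42)
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth, b$truth)
  c <- simulate_ph_trace(p, proto, seed = 43)
  expect_false(identical(a$trace$value, c$trace$value))
})

test_that("noise- and bleach-free traces are exact closed forms of the parameters", {
  p <- noise_free_params()
  proto <- short_protocol(rounds = 1, reference = FALSE)
  sim <- simulate_ph_trace(p, proto, seed = 1, capacity_override = 1,
                           gain = 1000, offset = 100, resting_surface = 0.08)
  tr <- sim$trace
  # baseline exactly offset + gain * resting surface
  expect_equal(unique(tr$value[tr$time_s < 120]), 100 + 1000 * 0.08)
  # NH4Cl plateau exactly offset + gain
  ep <- proto$nh4cl_epoch
  expect_equal(unique(tr$value[tr$time_s >= ep[1] & tr$time_s <= ep[2]]), 1100)
  # first-round normalized peak equals the per-round pool fraction (15%)
  norm <- normalize_to_total_pool(tr, proto)
  rounds <- segment_rounds(norm, proto)
  expect_equal(rounds$peak_value[1], 15, tolerance = 1e-6)
})

test_that("ph simulation records a ground-truth arrest round consistent with its EBs", {
  sim <- simulate_ph_neurons("da_gpi", n_neurons = 2, seed = 3,
                             protocol = endurance_protocol(rounds = 5, glucose_mM = 0))
  expect_equal(nrow(sim$truth), 2)
  expect_true(all(sim$rounds$eb_true >= 0 & sim$rounds$eb_true <= 100))
  for (id in sim$truth$neuron_id) {
    ebs <- sim$rounds$eb_true[sim$rounds$neuron_id == id]
    hit <- which(ebs > 50)
    want <- if (length(hit)) hit[1] else 5L
    expect_equal(sim$truth$arrest_round_true[sim$truth$neuron_id == id], want)
  }
})

test_that("a state that does not cover the protocol span is rejected", {
  p <- noise_free_params()
  proto_short <- short_protocol(rounds = 1)
  proto_long <- short_protocol(rounds = 3)
  st <- simulate_terminal_state(p, proto_short)
  expect_error(simulate_ph_trace(p, proto_long, state = st), "span")
})

test_that("ATP sensor ratio traces cancel expression and bleaching", {
  p <- noise_free_params(bleach_rate = 1e-4)
  proto <- atp_protocol(glucose_mM = 0)
  sim <- simulate_atp_ratio_traces(p, proto, n_rois = 5, seed = 2)
  ratio <- compute_ratio(sim$trace, reference_floor = 1e-6)
  wide <- tidyr::pivot_wider(ratio, names_from = roi_id, values_from = value)
  mat <- as.matrix(wide[, -(1:2)])
  # noise off: every ROI has the same ratio despite lognormal amplitudes
  expect_lt(max(apply(mat, 1, sd)), 1e-12)
  # the ratio recovers the saturating image of the ATP trajectory up to gain
  r <- mat[, 1] / mat[1, 1]
  truth <- sim$truth$sensor_signal / sim$truth$sensor_signal[1]
  expect_equal(r, truth, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ATP trace generator enforces its preconditions and ROI defaults", {
  p <- noise_free_params()
  expect_error(simulate_atp_ratio_traces(p, atp_protocol(), n_rois = 0), "n_rois")
  expect_true(
    eval(formals(simulate_atp_ratio_traces)$n_rois) >= 40 &&
      eval(formals(simulate_atp_ratio_traces)$n_rois) <= 60
  )
})

test_that("constant ATP gives a constant ratio trace", {
  p <- noise_free_params(glucose_mM = 5)
  proto <- stim_protocol(
    rounds = 1, rounds_start = 100, reference_round_start = NULL,
    glucose_timeline = tibble::tibble(start_s = 0, glucose_mM = 5),
    span_s = 200, frame_interval = 1
  )
  st <- simulate_terminal_state(p, proto)
  st$atp <- rep(1, nrow(st)) # pin ATP
  sim <- simulate_atp_ratio_traces(p, proto, n_rois = 3, seed = 1, state = st)
  ratio <- compute_ratio(sim$trace, reference_floor = 1e-6)
  expect_lt(diff(range(ratio$value)), 1e-12)
})
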