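make_two_channel <- function(tt, sensor, reference, roi = "r1") {
  dplyr::bind_rows(
    tibble::tibble(time_s = tt, roi_id = roi, channel = "sensor", value = sensor),
    tibble::tibble(time_s = tt, roi_id = roi, channel = "reference", value = reference)
  )
}

test_that("ratio computation handles proportional channels and masking", {
  tt <- seq(0, 99)
  ref <- 100 + sin(tt / 5)
  # sensor = reference -> ratio identically 1
  r1 <- compute_ratio(make_two_channel(tt, ref, ref), reference_floor = 1)
  expect_true(all(abs(r1$value - 1) < 1e-12))
  # sensor = 2 x reference -> ratio identically 2
  r2 <- compute_ratio(make_two_channel(tt, 2 * ref, ref), reference_floor = 1)
  expect_true(all(abs(r2$value - 2) < 1e-12))
  # shared multiplicative bleaching cancels exactly
  bleach <- exp(-1e-3 * tt)
  r3 <- compute_ratio(make_two_channel(tt, 2 * ref * bleach, ref * bleach),
                      reference_floor = 1)
  expect_equal(r3$value, r2$value)

  # frames with the reference at zero are masked, not divided
  ref0 <- ref
  ref0[10:12] <- 0
  r4 <- compute_ratio(make_two_channel(tt, ref0, ref0), reference_floor = 1)
  expect_equal(attr(r4, "n_masked"), 3)
  expect_true(all(is.na(r4$value[10:12])))

  # fully masked trace errors
  expect_error(
    compute_ratio(make_two_channel(tt, ref, rep(0, 100)), reference_floor = 1),
    "All frames masked"
  )
  # missing channel errors
  expect_error(
    compute_ratio(tibble::tibble(time_s = tt, roi_id = "r", channel = "sensor", value = ref)),
    "both channels"
  )
})

test_that("neuron averaging reproduces a single ROI and normalizes its baseline to 100%", {
  proto <- atp_protocol()
  tt <- seq(0, proto$span_s)
  v <- ifelse(tt >= 360 & tt < 420, 0.8, 1) * 2.4
  one <- tibble::tibble(time_s = tt, roi_id = "r1", channel = "ratio", value = v)
  many <- dplyr::bind_rows(lapply(sprintf("r%d", 1:5), function(id) {
    dplyr::mutate(one, roi_id = id)
  }))
  n1 <- neuron_average_and_baseline(one, proto)
  n5 <- neuron_average_and_baseline(many, proto)
  expect_equal(n1$value, n5$value)
  base <- n1$value[n1$time_s < 360 & n1$time_s >= 300]
  expect_equal(mean(base), 100)

  # empty baseline window errors
  late <- dplyr::filter(one, time_s >= 360)
  expect_error(neuron_average_and_baseline(late, proto), "Baseline|baseline")
})

test_that("phase decomposition reads drop and recovery from the declared windows", {
  proto <- atp_protocol()
  tt <- seq(0, proto$span_s)
  # constant trace: drop 0, recovery 100
  flat <- tibble::tibble(time_s = tt, value = rep(100, length(tt)))
  ph <- atp_phases(flat, proto)
  expect_equal(ph$baseline_percent, 100)
  expect_equal(ph$drop_percent, 0)
  expect_equal(ph$recovery_percent, 100)

  # dip to 80% during the train, then return: drop 20, recovery 100
  v <- rep(100, length(tt))
  v[tt >= 380 & tt <= 410] <- 80
  dip <- tibble::tibble(time_s = tt, value = v)
  ph2 <- atp_phases(dip, proto)
  expect_equal(ph2$drop_percent, 20)
  expect_equal(ph2$recovery_percent, 100)
  expect_true(ph2$t_min >= 380 && ph2$t_min <= 410)

  # windows outside the trace error
  expect_error(atp_phases(dplyr::filter(dip, time_s < 300), proto), "outside")

  # the "end" read-out convention is exposed
  ph3 <- atp_phases(dip, proto, drop_mode = "end")
  expect_equal(ph3$t_min, 420)
})

test_that("phase decomposition is invariant to extra trace length beyond the windows", {
  proto <- atp_protocol()
  tt <- seq(0, proto$span_s + 500)
  v <- 100 - 15 * exp(-((tt - 415) / 30)^2)
  tr <- tibble::tibble(time_s = tt, value = v)
  a <- atp_phases(dplyr::filter(tr, time_s <= proto$span_s), proto)
  b <- atp_phases(tr, proto)
  expect_equal(a$drop_percent, b$drop_percent)
})

test_that("noise-free synthetic input yields drop equal to the saturating map of min ATP", {
  p <- noise_free_params()
  proto <- atp_protocol(glucose_mM = 0)
  sim <- simulate_atp_ratio_traces(p, proto, n_rois = 10, seed = 3)
  neuron <- sim$trace |>
    compute_ratio(reference_floor = 1e-9) |>
    neuron_average_and_baseline(proto)
  ph <- atp_phases(neuron, proto)
  # oracle: invert the (known) saturating sensor map on the true trajectory
  sat <- function(a) a / (a + p$sensor_kd)
  tw <- sim$truth$time_s
  base_true <- mean(sat(sim$truth$atp[tw < 360 & tw >= 300]))
  w <- tw >= 360 & tw <= 430
  drop_true <- 100 * (1 - min(sat(sim$truth$atp[w])) / base_true)
  expect_equal(ph$drop_percent, drop_true, tolerance = 1e-6)
})

test_that("heterogeneous noisy ROIs average close to the noise-free neuron signal", {
  p <- condition_presets("glut_0gluc")
  proto <- atp_protocol(glucose_mM = 0)
  st <- simulate_terminal_state(p, proto, efficiency = 1)
  sim <- simulate_atp_ratio_traces(p, proto, n_rois = 50, seed = 8, state = st)
  neuron <- sim$trace |>
    compute_ratio() |>
    neuron_average_and_baseline(proto)
  sat <- sim$truth$sensor_signal
  base <- mean(sat[sim$truth$time_s < 360 & sim$truth$time_s >= 300])
  clean <- 100 * sat / base
  rms <- sqrt(mean((neuron$value - clean)^2)) / 100
  expect_lt(rms, 0.02)
})
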