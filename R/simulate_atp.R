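#' Simulate two-channel ATP-sensor ROI traces
#'
#' Generates per-ROI imaging-pair traces emulating an intensiometric ATP
#' sensor co-expressed with a spectrally separate reference fluorophore. The
#' sensor channel follows the simulated ATP trajectory through a saturating
#' binding curve `atp / (atp + sensor_kd)`; the reference channel has a
#' constant mean. Both channels share the per-ROI expression amplitude
#' (lognormal across ROIs) and the same multiplicative photobleaching, and
#' carry independent additive Gaussian noise — so their ratio cancels
#' expression level and bleaching, which is the point of ratiometric
#' reporting.
#'
#' @param params A [sim_params()] object.
#' @param protocol A [stim_protocol()], typically [atp_protocol()].
#' @param n_rois Number of circular ROIs (axonal varicosities); imaging
#'   practice uses 40-60 per neuron, default 50.
#' @param seed Integer seed.
#' @param state Optional precomputed [simulate_terminal_state()] trajectory.
#' @param roi_amp_sdlog Lognormal sdlog of per-ROI expression amplitude.
#' @param sensor_gain,reference_level Mean raw intensities (arbitrary units)
#'   of a unit-amplitude ROI.
#'
#' @return An object of class `atp_sim`: list with
#'   * `trace` — tibble `(time_s, roi_id, channel, value)` with channels
#'     `"sensor"` and `"reference"`;
#'   * `truth` — tibble `(time_s, atp, sensor_signal)` holding the noise-free
#'     ATP trajectory and its saturating-map image, plus attribute
#'     `"efficiency"`.
#' @export
simulate_atp_ratio_traces <- function(params, protocol, n_rois = 50, seed = 1,
                                      state = NULL,
                                      roi_amp_sdlog = 0.4,
                                      sensor_gain = 400,
                                      reference_level = 300) {
  stopifnot(inherits(params, "sim_params"), inherits(protocol, "stim_protocol"))
  if (n_rois < 1) abort("`n_rois` must be at least 1.")
  n_rois <- as.integer(n_rois)
  if (is.null(state)) {
    state <- simulate_terminal_state(params, protocol, seed = seed)
  }
  time_s <- state$time_s
  n <- length(time_s)
  sat <- state$atp / (state$atp + params$sensor_kd)
  bleach <- exp(-params$bleach_rate * time_s)

  amps <- with_seed(derive_seed(seed, 303), exp(rnorm(n_rois, 0, roi_amp_sdlog)))
  noise_sd <- params$noise_sd
  per_roi <- purrr::map(seq_len(n_rois), function(i) {
    noise <- if (noise_sd > 0) {
      with_seed(
        derive_seed(seed, 304, i),
        matrix(rnorm(2 * n, 0, noise_sd), ncol = 2)
      )
    } else {
      matrix(0, n, 2)
    }
    sensor <- amps[i] * sensor_gain * sat * bleach * (1 + noise[, 1])
    reference <- amps[i] * reference_level * bleach * (1 + noise[, 2])
    tibble(
      time_s = rep(time_s, 2),
      roi_id = sprintf("roi_%02d", i),
      channel = rep(c("sensor", "reference"), each = n),
      value = c(sensor, reference)
    )
  })
  truth <- tibble(time_s = time_s, atp = state$atp, sensor_signal = sat)
  attr(truth, "efficiency") <- attr(state, "efficiency")
  structure(
    list(trace = purrr::list_rbind(per_roi), truth = truth),
    class = "atp_sim"
  )
}
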