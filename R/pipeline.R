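#' Run a complete synthetic-experiment pipeline from a config
#'
#' Orchestrates simulate -> extract -> analyze -> compare for a declared set
#' of experimental arms: each arm names a condition preset, a cohort of
#' synthetic neurons is generated and analyzed, and every arm is compared to
#' the first (reference) arm with the Wilcoxon-Mann-Whitney test. The config
#' is validated — including every preset name — before any simulation runs,
#' and every decision parameter (thresholds, windows, seeds) is echoed into
#' the report, which is byte-identical across runs with the same seed.
#'
#' @param config A list, or path to a YAML file, with fields:
#'   * `analysis` — `"endurance"` (pHluorin rounds-to-block) or `"atp"`
#'     (ratiometric phase decomposition of the long-train paradigm);
#'   * `arms` — named list mapping arm label to a preset name
#'     (see [condition_presets()]); the first arm is the reference;
#'   * `n_per_arm` — neurons per arm (default 10);
#'   * `eb_threshold`, `max_rounds` — endurance settings (defaults 50, 30);
#'   * `alternative` — test sidedness (default `"two.sided"`).
#' @param seed Integer master seed for all randomness.
#' @param out_dir Optional directory; when given, writes `report.json`,
#'   `per_neuron.csv` and (for endurance) `per_round.csv`.
#' @return A report list: `analysis`, `seed`, `settings`, `arms` (per-arm
#'   summaries), `per_neuron` (tibble), `comparisons` (tibble).
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  analysis <- config$analysis %||% "endurance"
  if (!analysis %in% c("endurance", "atp")) {
    abort("`config$analysis` must be 'endurance' or 'atp'.")
  }
  arms <- config$arms
  if (is.null(arms) || length(arms) < 2 || is.null(names(arms)) || any(names(arms) == "")) {
    abort("`config$arms` must be a named list of at least two condition presets.")
  }
  # validate everything before any compute
  arm_params <- lapply(arms, function(p) condition_presets(p))
  n_per_arm <- config$n_per_arm %||% 10
  check_number(n_per_arm, "n_per_arm", min = 2)
  eb_threshold <- config$eb_threshold %||% 50
  max_rounds <- config$max_rounds %||% 30
  alternative <- config$alternative %||% "two.sided"

  per_neuron <- purrr::imap(arms, function(preset, arm) {
    params <- arm_params[[arm]]
    arm_seed <- derive_seed(seed, match(arm, names(arms)))
    if (analysis == "endurance") {
      protocol <- endurance_protocol(rounds = max_rounds, glucose_mM = params$glucose_mM)
      sim <- simulate_ph_neurons(preset, n_neurons = n_per_arm, seed = arm_seed,
                                 protocol = protocol)
      res <- analyze_endurance(sim$trace, protocol,
                               eb_threshold = eb_threshold, max_rounds = max_rounds)
      dplyr::mutate(res$per_neuron, arm = arm, preset = preset,
                    value = as.numeric(.data$rounds_to_block), .before = 1) |>
        dplyr::mutate(per_round = list(res$per_round))
    } else {
      protocol <- atp_protocol(glucose_mM = params$glucose_mM)
      purrr::map(seq_len(n_per_arm), function(i) {
        sim <- simulate_atp_ratio_traces(params, protocol,
                                         seed = derive_seed(arm_seed, i))
        phases <- sim$trace |>
          compute_ratio() |>
          neuron_average_and_baseline(protocol) |>
          atp_phases(protocol)
        dplyr::mutate(phases, neuron_id = sprintf("%s_%02d", arm, i))
      }) |>
        purrr::list_rbind() |>
        dplyr::mutate(arm = arm, preset = preset,
                      value = .data$drop_percent, .before = 1)
    }
  })
  per_round <- if (analysis == "endurance") {
    purrr::list_rbind(purrr::imap(per_neuron, function(df, arm) {
      dplyr::mutate(df$per_round[[1]], arm = arm, .before = 1)
    }))
  }
  per_neuron <- purrr::list_rbind(per_neuron)
  if (analysis == "endurance") per_neuron$per_round <- NULL

  arm_summaries <- purrr::imap(arms, function(preset, arm) {
    vals <- per_neuron$value[per_neuron$arm == arm]
    s <- summarize_group(vals)
    out <- list(
      arm = arm, preset = preset, n = s$n,
      mean = s$mean, sem = s$sem, label = s$label
    )
    if (analysis == "endurance") {
      out$n_censored <- sum(per_neuron$censored[per_neuron$arm == arm])
    }
    out
  })

  ref <- names(arms)[1]
  comparisons <- purrr::map(setdiff(names(arms), ref), function(arm) {
    mw <- mann_whitney_u(
      per_neuron$value[per_neuron$arm == ref],
      per_neuron$value[per_neuron$arm == arm],
      alternative = alternative
    )
    dplyr::mutate(mw, group1 = ref, group2 = arm, .before = 1)
  }) |> purrr::list_rbind()

  report <- list(
    analysis = analysis,
    seed = seed,
    settings = list(
      n_per_arm = n_per_arm,
      eb_threshold = eb_threshold,
      max_rounds = max_rounds,
      alternative = alternative,
      measure = if (analysis == "endurance") "rounds_to_block" else "drop_percent"
    ),
    arms = unname(arm_summaries),
    comparisons = comparisons,
    per_neuron = per_neuron
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report[c("analysis", "seed", "settings", "arms", "comparisons")],
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    utils::write.csv(per_neuron, file.path(out_dir, "per_neuron.csv"), row.names = FALSE)
    if (analysis == "endurance") {
      utils::write.csv(per_round, file.path(out_dir, "per_round.csv"), row.names = FALSE)
    }
  }
  report
}
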