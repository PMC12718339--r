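#' Parameters of the nerve-terminal bioenergetic model
#'
#' All quantities are dimensionless unless noted. ATP is expressed relative to
#' its resting level (1 = rest), the glycogen store relative to a full store
#' (1 = full), and the vesicle pool relative to total sensor-labelled pool
#' (1 = everything). The model couples three pools: cytosolic ATP, the
#' glycogen reserve, and surface-stranded (exocytosed, not yet retrieved)
#' sensor signal.
#'
#' ATP is consumed by a constant resting drain (`atp_rest_cost`), a per-AP
#' cost during stimulation (`atp_cost_per_ap`), and a vesicle-retrieval cost
#' proportional to the pool currently awaiting endocytosis (`recycle_cost`
#' ATP units per pool unit retrieved). Consumption tapers linearly once ATP
#' falls below `consumption_knee` (a crude stand-in for metabolism slowing
#' as substrates run out). ATP is produced from bath glucose
#' (`glucose_uptake_gain` per mM) and, whenever glucose is low, from
#' glycogenolysis at rate `gp_activity * gp_rate * glycogen`; each ATP unit
#' produced that way consumes `glycogen_per_atp` store units. Endocytic
#' capacity is a Hill function of ATP with midpoint `atp_capacity_halfpoint`
#' and coefficient `hill_n`: below the midpoint, vesicle retrieval collapses
#' sharply, which is what the endocytic-block statistic detects.
#'
#' @param glycogen_store_0 Initial glycogen store in `[0, 1]`.
#' @param gp_activity Glycogen phosphorylase activity in `[0, 1]`
#'   (1 = untreated dopaminergic neurons; 0.5 = knockdown; 0 = full
#'   pharmacological inhibition).
#' @param gp_rate Maximal glycogenolytic ATP production per second at a full
#'   store and `gp_activity = 1`.
#' @param glucose_uptake_gain ATP production per second per mM bath glucose.
#' @param atp_rest_cost Resting ATP consumption per second.
#' @param atp_cost_per_ap ATP consumed per action potential.
#' @param recycle_cost ATP consumed per unit of vesicle pool retrieved.
#' @param endocytosis_tau Re-acidification/retrieval time constant (seconds).
#' @param atp_capacity_halfpoint,hill_n Hill map from relative ATP to
#'   endocytic capacity.
#' @param exo_pool_fraction_per_round Fraction of the not-yet-stranded pool
#'   exocytosed by one 50-AP round.
#' @param consumption_knee Relative ATP level below which consumption tapers.
#' @param glycogen_per_atp Store units consumed per glycogenolytic ATP unit.
#' @param neuron_cv Lognormal sdlog of the per-neuron metabolic-efficiency
#'   factor (scales glycogen yield), generating the cell-to-cell endurance
#'   spread seen across neurons.
#' @param noise_sd Additive Gaussian fluorescence noise, as a fraction of the
#'   first-round peak amplitude.
#' @param bleach_rate Shared multiplicative photobleaching rate (per second).
#' @param sensor_kd Half-saturation of the intensiometric ATP sensor, on the
#'   relative-ATP scale (weakly saturating by default).
#' @param d2r_tone D2-autoreceptor tone in `[0, 1]`; the effective initial
#'   store is `glycogen_store_0 * d2r_tone` (chronic antagonism depletes the
#'   reserve).
#' @param glucose_mM Default bath glucose (mM) used when a protocol is built
#'   for this condition.
#'
#' @return A validated `sim_params` object (a list).
#' @seealso [condition_presets()] for the named experimental conditions.
#' @export
sim_params <- function(glycogen_store_0 = 1,
                       gp_activity = 1,
                       gp_rate = 0.0175,
                       glucose_uptake_gain = 0.004,
                       atp_rest_cost = 0.007,
                       atp_cost_per_ap = 0.0005,
                       recycle_cost = 0.35,
                       endocytosis_tau = 8,
                       atp_capacity_halfpoint = 0.7,
                       hill_n = 6,
                       exo_pool_fraction_per_round = 0.15,
                       consumption_knee = 0.5,
                       glycogen_per_atp = 0.032,
                       neuron_cv = 0.5,
                       noise_sd = 0.05,
                       bleach_rate = 2e-5,
                       sensor_kd = 3,
                       d2r_tone = 1,
                       glucose_mM = 0) {
  p <- list(
    glycogen_store_0 = glycogen_store_0,
    gp_activity = gp_activity,
    gp_rate = gp_rate,
    glucose_uptake_gain = glucose_uptake_gain,
    atp_rest_cost = atp_rest_cost,
    atp_cost_per_ap = atp_cost_per_ap,
    recycle_cost = recycle_cost,
    endocytosis_tau = endocytosis_tau,
    atp_capacity_halfpoint = atp_capacity_halfpoint,
    hill_n = hill_n,
    exo_pool_fraction_per_round = exo_pool_fraction_per_round,
    consumption_knee = consumption_knee,
    glycogen_per_atp = glycogen_per_atp,
    neuron_cv = neuron_cv,
    noise_sd = noise_sd,
    bleach_rate = bleach_rate,
    sensor_kd = sensor_kd,
    d2r_tone = d2r_tone,
    glucose_mM = glucose_mM
  )
  for (nm in names(p)) check_number(p[[nm]], nm, min = 0)
  for (nm in c("glycogen_store_0", "gp_activity", "d2r_tone",
               "exo_pool_fraction_per_round", "consumption_knee")) {
    check_number(p[[nm]], nm, min = 0, max = 1)
  }
  check_number(p$endocytosis_tau, "endocytosis_tau", min = 0, strict_min = TRUE)
  check_number(p$hill_n, "hill_n", min = 0, strict_min = TRUE)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  flat <- unlist(unclass(x))
  for (nm in names(flat)) cat(sprintf("  %-28s %g\n", nm, flat[nm]))
  invisible(x)
}

# Effective initial glycogen store after D2R tone scaling, bounded in [0, 1].
initial_store <- function(params) {
  min(1, params$glycogen_store_0 * params$d2r_tone)
}

#' Named experimental-condition presets
#'
#' Returns the full simulation parameter set for one of the named
#' experimental conditions. Presets differ only in the interpretable fields:
#' glycogen phosphorylase activity (`gp_activity`), the glycogen reserve
#' (via `glycogen_store_0`/`d2r_tone`), and bath glucose:
#'
#' * `da_0gluc` — untreated dopaminergic neurons, glucose-free saline
#'   (the control arm of the endurance assay).
#' * `da_5gluc` — dopaminergic neurons in 5 mM glucose.
#' * `da_gpi` — acute small-molecule glycogen phosphorylase inhibitor:
#'   `gp_activity = 0`.
#' * `da_gpkd` — shRNA knockdown of glycogen phosphorylase (about half the
#'   enzyme remains): `gp_activity = 0.5`.
#' * `da_sulpiride` — overnight D2R antagonism; the autocrine signal that
#'   maintains the reserve is lost and the store is roughly halved
#'   (`d2r_tone = 0.546`, i.e. a 45.4% reduction).
#' * `glut_0gluc` — glutamatergic (hippocampal) neurons, glucose-free saline:
#'   a smaller usable reserve and less engaged glycogenolysis.
#'
#' @param name One of the preset names above.
#' @return A [sim_params()] object.
#' @export
condition_presets <- function(name) {
  presets <- list(
    da_0gluc = sim_params(),
    da_5gluc = sim_params(glucose_mM = 5),
    da_gpi = sim_params(gp_activity = 0),
    da_gpkd = sim_params(gp_activity = 0.5),
    da_sulpiride = sim_params(d2r_tone = 0.546),
    glut_0gluc = sim_params(gp_activity = 0.5, glycogen_store_0 = 0.95)
  )
  if (length(name) != 1 || !is.character(name) || !name %in% names(presets)) {
    abort(sprintf(
      "Unknown condition preset %s. Valid presets: %s.",
      sQuote(paste(as.character(name), collapse = ",")),
      paste(sQuote(names(presets)), collapse = ", ")
    ))
  }
  presets[[name]]
}

#' @rdname condition_presets
#' @export
preset_names <- function() {
  c("da_0gluc", "da_5gluc", "da_gpi", "da_gpkd", "da_sulpiride", "glut_0gluc")
}

#' Read or write simulation parameters as YAML
#'
#' One YAML document per condition; the files shipped under
#' `system.file("extdata", "presets", package = "synendure")` are the
#' serialized forms of [condition_presets()].
#'
#' @param params A [sim_params()] object.
#' @param path File path.
#' @return `write_params_yaml()` returns `path` invisibly;
#'   `read_params_yaml()` a [sim_params()].
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  do.call(sim_params, yaml::read_yaml(path))
}
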