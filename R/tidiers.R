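# broom-style tidiers for the package's result objects.

#' Tidy an endurance analysis into per-round rows
#'
#' @param x An `endurance_analysis` from [analyze_endurance()].
#' @param ... Unused.
#' @return The per-round tibble (`neuron_id`, `round_index`, peaks,
#'   `eb_percent`).
#' @method tidy endurance_analysis
#' @export
tidy.endurance_analysis <- function(x, ...) {
  x$per_round
}

#' One-row summary of an endurance analysis
#'
#' @param x An `endurance_analysis`.
#' @param ... Unused.
#' @return One-row tibble: `n_neurons`, `mean_rounds`, `sem_rounds`,
#'   `n_censored`, `mean_tau_ref`, `threshold`, `max_rounds`, `label`.
#' @method glance endurance_analysis
#' @export
glance.endurance_analysis <- function(x, ...) {
  s <- summarize_group(x$per_neuron$rounds_to_block)
  tibble(
    n_neurons = s$n,
    mean_rounds = s$mean,
    sem_rounds = s$sem,
    n_censored = sum(x$per_neuron$censored),
    mean_tau_ref = mean(x$per_neuron$tau_ref),
    threshold = x$threshold,
    max_rounds = x$max_rounds,
    label = s$label
  )
}

#' Tidy the glycogen-GS regression coefficients
#'
#' @param x A `gs_relation` from [glycogen_gs_relation()].
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @method tidy gs_relation
#' @export
tidy.gs_relation <- function(x, ...) {
  co <- summary(x$model)$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    statistic = co[, "t value"],
    p_value = co[, "Pr(>|t|)"]
  )
}

#' One-row summary of the glycogen-GS relation
#'
#' @param x A `gs_relation`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `slope`, `intercept`, `r_squared`,
#'   `n_bins`, `bin_width`.
#' @method glance gs_relation
#' @export
glance.gs_relation <- function(x, ...) {
  co <- coef(x$model)
  tibble(
    n = nrow(x$records),
    slope = unname(co[2]),
    intercept = unname(co[1]),
    r_squared = summary(x$model)$r.squared,
    n_bins = nrow(x$bins),
    bin_width = x$bin_width
  )
}

#' Tidy per-coverslip TH+/TH- ratios
#'
#' @param x A `th_ratio` from [th_ratio()].
#' @param ... Unused.
#' @return The per-coverslip tibble.
#' @method tidy th_ratio
#' @export
tidy.th_ratio <- function(x, ...) {
  x$per_coverslip
}

#' One-row summary of the TH+/TH- ratio analysis
#'
#' @param x A `th_ratio`.
#' @param ... Unused.
#' @return One-row tibble: `n_coverslips`, `mean_ratio`, `sem`,
#'   `n_excluded`, `label`.
#' @method glance th_ratio
#' @export
glance.th_ratio <- function(x, ...) {
  tibble(
    n_coverslips = x$summary$n,
    mean_ratio = x$summary$mean,
    sem = x$summary$sem,
    n_excluded = x$n_excluded,
    label = x$summary$label
  )
}
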