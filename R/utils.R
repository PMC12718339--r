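# Internal helpers shared across modules.

# Deterministic child seeds: one user-facing seed fans out to independent
# streams (per neuron, per coverslip, ...) without seed reuse across stages.
# Values stay inside the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, ...) {
  key <- c(seed, ...)
  x <- 0
  # multiplier kept small so x * mult + k stays exact in double precision
  m <- 2147483647
  for (k in key) {
    x <- (x * 69069 + (as.numeric(k) %% m) + 12345) %% m
  }
  as.integer(x)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || (strict_min && x <= min) || x > max) {
    abort(sprintf(
      "`%s` = %g is outside its valid range %s%g, %g].",
      name, x, if (strict_min) "(" else "[", min, max
    ))
  }
  invisible(x)
}

# Hill function mapping relative ATP to endocytic capacity in [0, 1].
hill_capacity <- function(atp, halfpoint, n) {
  atp <- pmax(atp, 0)
  atp^n / (atp^n + halfpoint^n)
}

assert_trace_tbl <- function(traces, required = c("time_s", "roi_id", "channel", "value")) {
  if (!is.data.frame(traces)) {
    abort("`traces` must be a data frame with columns time_s, roi_id, channel, value.")
  }
  missing <- setdiff(required, names(traces))
  if (length(missing)) {
    abort(sprintf("`traces` is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  invisible(traces)
}
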