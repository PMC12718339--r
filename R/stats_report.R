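#' Wilcoxon-Mann-Whitney rank test
#'
#' Two-sample rank test with mid-ranks for ties. For small samples (both
#' sizes at most `exact_limit`) the p-value is exact, computed by full
#' enumeration of all `choose(n1 + n2, n1)` assignments of the pooled
#' mid-ranks — which remains exact in the presence of ties, where the
#' classical null tables do not apply. Larger samples use the normal
#' approximation with tie-corrected variance and a continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   referring to the location of `x` relative to `y`.
#' @param exact_limit Exact enumeration is used when `n1 <= exact_limit` and
#'   `n2 <= exact_limit` (default 8).
#' @return One-row tibble: `n1`, `n2`, `u` (the Mann-Whitney U of `x`),
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`), `alternative`,
#'   `stars`. `U(x, y) + U(y, x) = n1 * n2` always.
#' @export
mann_whitney_u <- function(x, y, alternative = c("two.sided", "less", "greater"),
                           exact_limit = 8) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]
  y <- y[is.finite(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0 || n2 == 0) abort("Both samples must be non-empty.")
  pooled <- c(x, y)
  r <- rank(pooled) # mid-ranks for ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 <= exact_limit && n2 <= exact_limit) {
    method <- "exact"
    combos <- combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    n_tot <- ncol(combos)
    eps <- 1e-9
    p_le <- sum(u_all <= u_obs + eps) / n_tot
    p_ge <- sum(u_all >= u_obs - eps) / n_tot
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      less = p_le,
      greater = p_ge
    )
  } else {
    method <- "normal_approx"
    n <- n1 + n2
    ties <- table(pooled)
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) abort("Degenerate samples: zero rank variance (all values tied).")
    z_num <- u_obs - mu
    cc <- switch(alternative,
      two.sided = sign(z_num) * 0.5,
      greater = 0.5,
      less = -0.5
    )
    z <- (z_num - cc) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)),
      less = pnorm(z),
      greater = pnorm(z, lower.tail = FALSE)
    )
    p <- min(1, max(p, .Machine$double.xmin))
  }
  tibble(
    n1 = n1, n2 = n2, u = u_obs, p_value = p,
    method = method, alternative = alternative,
    stars = significance_stars(p)
  )
}

#' Group summary as mean +/- SEM
#'
#' @param values Numeric sample (non-empty).
#' @return One-row tibble: `n`, `mean`, `sem` (sample sd / sqrt(n), `NA`
#'   with `sem_defined = FALSE` when n = 1), and a formatted `label` such
#'   as `"5.95 ± 0.45"`.
#' @export
summarize_group <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) abort("`values` is empty.")
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2) sd(values) / sqrt(n) else NA_real_
  tibble(
    n = n, mean = m, sem = s, sem_defined = n >= 2,
    label = format_mean_sem(m, s)
  )
}

#' Format a mean and SEM the way figure legends print them
#'
#' @param mean,sem Numbers; `sem` may be `NA`.
#' @param digits Significant digits (default 3).
#' @return A string like `"18.66 ± 1.69"` (or just the mean when SEM is
#'   undefined).
#' @export
format_mean_sem <- function(mean, sem, digits = 3) {
  if (is.na(sem)) {
    format(signif(mean, digits))
  } else {
    sprintf("%s ± %s", format(signif(mean, digits)), format(signif(sem, digits)))
  }
}

#' Significance stars for a p-value
#'
#' The usual star convention: `p >= 0.05` is `"ns"`, then one to four
#' asterisks at thresholds 0.05, 0.01, 0.001 and 0.0001.
#'
#' @param p A p-value in `(0, 1]` (vectorized).
#' @return Character vector of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  dplyr::case_when(
    p < 0.0001 ~ "****",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Compare two groups of a tidy data frame
#'
#' Mean +/- SEM per group plus the Wilcoxon-Mann-Whitney test between them.
#'
#' @param data A data frame.
#' @param value Name of the numeric outcome column.
#' @param group Name of the two-level grouping column.
#' @param reference Optional level treated as group 1 (`x` in
#'   [mann_whitney_u()]); defaults to the first level encountered.
#' @param ... Passed to [mann_whitney_u()].
#' @return One-row tibble with group labels, per-group `n`/`mean`/`sem`,
#'   `u`, `p_value`, `method`, `stars`.
#' @export
compare_groups <- function(data, value, group, reference = NULL, ...) {
  v <- data[[value]]
  g <- as.character(data[[group]])
  levels <- unique(g)
  if (length(levels) != 2) {
    abort(sprintf("`%s` must have exactly 2 levels, found %d.", group, length(levels)))
  }
  if (!is.null(reference)) {
    if (!reference %in% levels) abort("`reference` is not a level of the grouping column.")
    levels <- c(reference, setdiff(levels, reference))
  }
  s1 <- summarize_group(v[g == levels[1]])
  s2 <- summarize_group(v[g == levels[2]])
  mw <- mann_whitney_u(v[g == levels[1]], v[g == levels[2]], ...)
  tibble(
    group1 = levels[1], group2 = levels[2],
    n1 = s1$n, mean1 = s1$mean, sem1 = s1$sem, label1 = s1$label,
    n2 = s2$n, mean2 = s2$mean, sem2 = s2$sem, label2 = s2$label,
    u = mw$u, p_value = mw$p_value, method = mw$method, stars = mw$stars
  )
}
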