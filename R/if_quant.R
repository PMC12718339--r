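#' Quantify per-cell immunofluorescence intensities
#'
#' Measures the mean intensity of every signal ROI in each channel of a
#' multi-channel image, subtracting the mean over the background ROIs of the
#' same channel. ROI annotation columns (e.g. `th_status`, `coverslip_id`,
#' `culture_id`, `compartment`) are carried through to the output records.
#'
#' @param image Numeric array `height x width x n_channels`, with channel
#'   names in `dimnames(image)[[3]]`, or a named list of matrices.
#' @param rois ROI table as in [extract_roi_traces()], plus any annotation
#'   columns.
#' @param channels Channel names to quantify; default all.
#' @return A tibble with one row per signal ROI: annotations plus one
#'   `<channel>` column of background-subtracted mean intensity each.
#' @export
quantify_cells <- function(image, rois, channels = NULL) {
  if (is.list(image) && !is.array(image)) {
    image <- simplify2array(image)
  }
  if (!is.array(image) || length(dim(image)) != 3) {
    abort("`image` must be a height x width x channels array or list of matrices.")
  }
  ch_names <- dimnames(image)[[3]] %||% sprintf("ch%d", seq_len(dim(image)[3]))
  channels <- channels %||% ch_names
  missing <- setdiff(channels, ch_names)
  if (length(missing)) {
    abort(sprintf(
      "Channel(s) %s not present in the image (has: %s).",
      paste(sQuote(missing), collapse = ", "), paste(sQuote(ch_names), collapse = ", ")
    ))
  }
  d <- dim(image)
  rois <- as_tibble(rois)
  validate_roi_set(rois, d[1], d[2])
  signal <- rois[rois$kind == "signal", ]
  bg <- rois[rois$kind == "background", ]
  if (!nrow(signal)) abort("No signal ROIs to quantify.")

  masks <- lapply(seq_len(nrow(rois)), function(i) {
    disk_mask(d[1], d[2], rois$center_x_px[i], rois$center_y_px[i], rois$radius_px[i])
  })
  names(masks) <- rois$roi_id

  vals <- purrr::map(channels, function(ch) {
    plane <- image[, , match(ch, ch_names)]
    bg_level <- if (nrow(bg)) {
      mean(vapply(bg$roi_id, function(id) mean(plane[masks[[id]]]), numeric(1)))
    } else {
      0
    }
    unname(vapply(signal$roi_id, function(id) mean(plane[masks[[id]]]) - bg_level, numeric(1)))
  })
  names(vals) <- channels
  dplyr::bind_cols(
    dplyr::select(signal, -dplyr::any_of(c("center_x_px", "center_y_px", "radius_px", "kind"))),
    as_tibble(vals)
  )
}

#' Normalize intensity records to their culture mean
#'
#' Fluorescence intensity in each channel is divided by the mean of that
#' channel over the corresponding culture batch, adding `<channel>_norm`
#' columns. By construction the normalized values of each culture average to
#' 1 per channel, making downstream statistics invariant to per-culture
#' staining or acquisition gain.
#'
#' @param records Output of [quantify_cells()] with a `culture_id` column.
#' @param channels Channels to normalize; default: all numeric measurement
#'   columns.
#' @return `records` with `<channel>_norm` columns appended.
#' @export
normalize_by_culture <- function(records, channels = NULL) {
  if (!"culture_id" %in% names(records)) {
    abort("`records` needs a `culture_id` column for culture normalization.")
  }
  known_meta <- c(
    "roi_id", "cell_id", "coverslip_id", "culture_id", "th_status",
    "compartment", "condition"
  )
  channels <- channels %||% setdiff(
    names(records)[vapply(records, is.numeric, logical(1))],
    known_meta
  )
  channels <- setdiff(channels, grep("_norm$", names(records), value = TRUE))
  records |>
    dplyr::group_by(.data$culture_id) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(channels),
      ~ .x / mean(.x),
      .names = "{.col}_norm"
    )) |>
    dplyr::ungroup()
}

#' Glycogen-glycogen synthase relation with binned means
#'
#' Ordinary least-squares fit of culture-normalized glycogen intensity on
#' culture-normalized glycogen synthase (GS) intensity across cells, plus
#' binned averages (mean +/- SEM of glycogen in fixed-width GS bins, edges
#' anchored at 0 and left-closed). Bins with fewer than 2 cells are flagged.
#'
#' @param records Records with the two normalized intensity columns.
#' @param gs,glycogen Column names (defaults `gs_norm`, `glycogen_norm`).
#' @param bin_width GS-axis bin width (default 0.5).
#' @return Object of class `gs_relation`: list with `model` (the `lm` fit),
#'   `bins` (tibble `gs_bin_mid`, `gs_mean`, `n`, `glycogen_mean`, `glycogen_sem`,
#'   `flagged`), `records`, `gs`, `glycogen`, `bin_width`. Supports
#'   [tidy()], [glance()], [ggplot2::autoplot()].
#' @export
glycogen_gs_relation <- function(records, gs = "gs_norm", glycogen = "glycogen_norm",
                                 bin_width = 0.5) {
  for (col in c(gs, glycogen)) {
    if (!col %in% names(records)) abort(sprintf("Column `%s` not found in records.", col))
  }
  records <- records[is.finite(records[[gs]]) & is.finite(records[[glycogen]]), ]
  if (nrow(records) < 10) abort("Need at least 10 records with both channels.")
  if (sd(records[[gs]]) == 0) abort("Degenerate GS spread (sd = 0); cannot fit.")
  model <- lm(stats::reformulate(gs, glycogen), data = records)
  bins <- records |>
    dplyr::mutate(.bin = floor(.data[[gs]] / bin_width)) |>
    dplyr::group_by(.data$.bin) |>
    dplyr::summarise(
      gs_bin_mid = (.data$.bin[1] + 0.5) * bin_width,
      gs_mean = mean(.data[[gs]]),
      n = dplyr::n(),
      glycogen_mean = mean(.data[[glycogen]]),
      glycogen_sem = sd(.data[[glycogen]]) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    dplyr::mutate(flagged = .data$n < 2) |>
    dplyr::select(-".bin")
  structure(
    list(
      model = model, bins = bins, records = records,
      gs = gs, glycogen = glycogen, bin_width = bin_width
    ),
    class = "gs_relation"
  )
}

#' @export
print.gs_relation <- function(x, ...) {
  co <- coef(x$model)
  cat("<gs_relation>\n")
  cat(sprintf(
    "  n = %d cells; glycogen = %.3g + %.3g * GS (normalized units); %d bins of width %g\n",
    nrow(x$records), co[1], co[2], nrow(x$bins), x$bin_width
  ))
  invisible(x)
}

#' Per-coverslip TH+/TH- intensity ratio
#'
#' For each coverslip, the ratio of mean glycogen intensity of TH-positive
#' cell bodies to TH-negative ones, summarized across coverslips as
#' mean +/- SEM. Any within-coverslip gain cancels in the ratio. Coverslips
#' lacking one of the two classes are excluded with a warning and counted.
#'
#' @param records Records with `coverslip_id`, `th_status` and the intensity
#'   column.
#' @param value Intensity column (default `glycogen_norm`).
#' @return Object of class `th_ratio`: list with `per_coverslip` (tibble
#'   `coverslip_id`, `n_positive`, `n_negative`, `ratio`), `summary`
#'   (mean, sem, n, label) and `n_excluded`.
#' @export
th_ratio <- function(records, value = "glycogen_norm") {
  for (col in c("coverslip_id", "th_status", value)) {
    if (!col %in% names(records)) abort(sprintf("Column `%s` not found in records.", col))
  }
  per <- records |>
    dplyr::group_by(.data$coverslip_id) |>
    dplyr::summarise(
      n_positive = sum(.data$th_status == "positive"),
      n_negative = sum(.data$th_status == "negative"),
      ratio = mean(.data[[value]][.data$th_status == "positive"]) /
        mean(.data[[value]][.data$th_status == "negative"]),
      .groups = "drop"
    )
  incomplete <- per$n_positive == 0 | per$n_negative == 0
  if (any(incomplete)) {
    warn(sprintf(
      "%d coverslip(s) lack a TH class and were excluded: %s.",
      sum(incomplete), paste(per$coverslip_id[incomplete], collapse = ", ")
    ))
  }
  kept <- per[!incomplete, ]
  if (!nrow(kept)) abort("No coverslip has both TH-positive and TH-negative cells.")
  structure(
    list(
      per_coverslip = kept,
      summary = summarize_group(kept$ratio),
      n_excluded = sum(incomplete)
    ),
    class = "th_ratio"
  )
}

#' @export
print.th_ratio <- function(x, ...) {
  cat("<th_ratio>\n")
  cat(sprintf(
    "  TH+/TH- ratio per coverslip: %s (n = %d coverslips%s)\n",
    x$summary$label, x$summary$n,
    if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""
  ))
  invisible(x)
}

#' Percent change of a treated group relative to control
#'
#' Treated intensities are normalized to the control-group mean (controls
#' from the same culture batch define the unit), and the effect is reported
#' as a percent reduction: `100 * (1 - mean(treated) / mean(control))`.
#' Positive values are reductions; a doubling reports -100 (an increase).
#' The SEM is propagated from the control-normalized treated values only.
#'
#' @param treated,control Numeric vectors of (raw or culture-normalized)
#'   intensities.
#' @return One-row tibble: `percent_reduction`, `sem`, `n_treated`,
#'   `n_control`, `direction` (`"reduction"`/`"increase"`/`"none"`),
#'   `label`.
#' @export
treatment_effect <- function(treated, control) {
  if (!length(treated) || !length(control)) abort("Both groups must be non-empty.")
  m_ctrl <- mean(control)
  if (!is.finite(m_ctrl) || m_ctrl <= 0) abort("Control mean must be positive.")
  rel <- treated / m_ctrl
  pct <- 100 * (1 - mean(rel))
  sem <- 100 * sd(rel) / sqrt(length(rel))
  tibble(
    percent_reduction = pct,
    sem = sem,
    n_treated = length(treated),
    n_control = length(control),
    direction = if (pct > 0) "reduction" else if (pct < 0) "increase" else "none",
    label = format_mean_sem(pct, sem)
  )
}
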