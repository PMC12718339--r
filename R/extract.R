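# ROI-trace extraction from image stacks.

# Logical mask of pixels whose centers fall within radius of (cx, cy).
# Pixel centers sit at integer + 0.5 in 0-based image coordinates
# (x = column, y = row), so pixel (row i, col j) has center (j - 0.5, i - 0.5)
# in 1-based R indexing.
disk_mask <- function(h, w, cx, cy, radius) {
  xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}

validate_roi_set <- function(rois, h, w) {
  req <- c("roi_id", "center_x_px", "center_y_px", "radius_px", "kind")
  missing <- setdiff(req, names(rois))
  if (length(missing)) {
    abort(sprintf("ROI table is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(rois$roi_id)) abort("ROI ids must be unique.")
  if (any(rois$radius_px <= 0)) abort("ROI radii must be positive.")
  bad <- rois$center_x_px - rois$radius_px < 0 |
    rois$center_x_px + rois$radius_px > w |
    rois$center_y_px - rois$radius_px < 0 |
    rois$center_y_px + rois$radius_px > h
  if (any(bad)) {
    abort(sprintf(
      "ROI(s) extend outside the %dx%d frame: %s.",
      h, w, paste(rois$roi_id[bad], collapse = ", ")
    ))
  }
  if (!all(rois$kind %in% c("signal", "background"))) {
    abort("ROI `kind` must be 'signal' or 'background'.")
  }
  invisible(rois)
}

#' Extract background-subtracted ROI traces from an image stack
#'
#' For each signal ROI and each frame, the trace value is the mean of the
#' pixels whose centers lie inside the ROI disk. The frame-wise background —
#' the mean over all background ROIs of the same frame — is subtracted,
#' unless `background = "none"`.
#'
#' @param stack Numeric array `height x width x n_frames` (a single-channel
#'   stack), or a named list of such arrays for multi-channel data.
#' @param rois ROI table with columns `roi_id`, `center_x_px`, `center_y_px`,
#'   `radius_px`, `kind` (`"signal"` or `"background"`). Coordinates are
#'   0-based with pixel centers at integer + 0.5; x indexes columns, y rows.
#' @param frame_interval Seconds between frames (builds the time axis).
#' @param background `"mean"` (default: subtract the per-frame mean of the
#'   background ROIs) or `"none"` (return raw disk means).
#' @param channel Channel label for single-array input.
#' @return A trace tibble `(time_s, roi_id, channel, value)` covering every
#'   signal ROI, with the background policy recorded in attribute
#'   `"background_policy"`.
#' @export
extract_roi_traces <- function(stack, rois, frame_interval = 1,
                               background = c("mean", "none"),
                               channel = "ph") {
  background <- match.arg(background)
  if (is.list(stack) && !is.array(stack)) {
    traces <- purrr::imap(stack, function(arr, ch) {
      extract_roi_traces(arr, rois, frame_interval, background, channel = ch)
    })
    out <- purrr::list_rbind(unname(traces))
    attr(out, "background_policy") <- background
    return(out)
  }
  if (!is.array(stack) || length(dim(stack)) != 3 || any(dim(stack) == 0)) {
    abort("`stack` must be a non-empty height x width x frames array.")
  }
  d <- dim(stack)
  rois <- as_tibble(rois)
  validate_roi_set(rois, d[1], d[2])
  signal <- rois[rois$kind == "signal", ]
  bg <- rois[rois$kind == "background", ]
  if (!nrow(signal)) abort("No signal ROIs in the ROI table.")
  if (background == "mean" && !nrow(bg)) {
    abort("No background ROIs; pass background = \"none\" to skip subtraction.")
  }

  flat <- matrix(stack, d[1] * d[2], d[3])
  roi_means <- function(tbl) {
    vapply(seq_len(nrow(tbl)), function(i) {
      m <- disk_mask(d[1], d[2], tbl$center_x_px[i], tbl$center_y_px[i], tbl$radius_px[i])
      if (!any(m)) abort(sprintf("ROI %s contains no pixel centers.", tbl$roi_id[i]))
      colMeans(flat[as.vector(m), , drop = FALSE])
    }, numeric(d[3]))
  }
  sig_means <- roi_means(signal) # frames x rois
  bg_trace <- if (background == "mean") rowMeans(roi_means(bg)) else rep(0, d[3])

  time_s <- (seq_len(d[3]) - 1) * frame_interval
  # column-major flattening of (frames x rois) matches expand_grid order
  out <- tidyr::expand_grid(roi_id = signal$roi_id, time_s = time_s) |>
    dplyr::mutate(
      channel = channel,
      value = as.vector(sig_means - bg_trace)
    ) |>
    dplyr::select("time_s", "roi_id", "channel", "value")
  attr(out, "background_policy") <- background
  out
}

#' Keep only ROIs that respond to the first stimulus train
#'
#' Nerve terminals are selected by their response to the first AP train
#' (delivered in 5 mM glucose when the protocol declares a reference round):
#' an ROI is kept when its mean rise during that train, relative to the
#' immediately preceding baseline, exceeds `k_sigma` times the baseline
#' standard deviation.
#'
#' @param traces A trace tibble `(time_s, roi_id, channel, value)`.
#' @param protocol A [stim_protocol()] whose first train lies inside the
#'   trace span.
#' @param k_sigma Threshold multiplier (default 2).
#' @param baseline_window Seconds of pre-train baseline used (default 10).
#' @return The trace tibble restricted to responding ROIs, with attributes
#'   `"n_kept"` and `"n_dropped"`. Selection is idempotent.
#' @export
select_responding_rois <- function(traces, protocol, k_sigma = 2,
                                   baseline_window = 10) {
  assert_trace_tbl(traces)
  trains <- protocol_trains(protocol)
  first <- trains[which.min(trains$t_start), ]
  span <- range(traces$time_s)
  if (first$t_start < span[1] || first$t_end > span[2]) {
    abort("The protocol's first train lies outside the trace span.")
  }
  stats_tbl <- traces |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(
      base_mean = mean(.data$value[.data$time_s < first$t_start &
        .data$time_s >= first$t_start - baseline_window]),
      base_sd = sd(.data$value[.data$time_s < first$t_start &
        .data$time_s >= first$t_start - baseline_window]),
      rise = mean(.data$value[.data$time_s >= first$t_start &
        .data$time_s <= first$t_end + 1]) - .data$base_mean,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      keep = .data$rise > 0 &
        (.data$base_sd == 0 | .data$rise > k_sigma * .data$base_sd)
    )
  kept <- stats_tbl$roi_id[stats_tbl$keep]
  if (!length(kept)) {
    abort(sprintf(
      "No ROI passed the responding criterion (k_sigma = %g); %d ROI(s) rejected.",
      k_sigma, nrow(stats_tbl)
    ))
  }
  out <- dplyr::filter(traces, .data$roi_id %in% kept)
  attr(out, "n_kept") <- length(kept)
  attr(out, "n_dropped") <- nrow(stats_tbl) - length(kept)
  out
}
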