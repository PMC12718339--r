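# Plain-text and TIFF interchange. Traces use one shared CSV schema
# (time_s, roi_id, channel, value) whether they come from the simulator or
# from extracted image stacks, so every downstream module is source-agnostic.

#' Read and write trace tables as CSV
#'
#' @param traces Trace tibble `(time_s, roi_id, channel, value)`.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   the validated trace tibble.
#' @export
write_trace_csv <- function(traces, path) {
  assert_trace_tbl(traces)
  utils::write.csv(
    traces[, c("time_s", "roi_id", "channel", "value")], path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  assert_trace_tbl(df)
  df$roi_id <- as.character(df$roi_id)
  df$channel <- as.character(df$channel)
  df
}

#' Read and write ROI tables as CSV
#'
#' The schema has the columns of [extract_roi_traces()]'s `rois` argument
#' (`roi_id`, `center_x_px`, `center_y_px`, `radius_px`, `kind`) plus any
#' annotation columns (`th_status`, `coverslip_id`, `culture_id`,
#' `compartment`).
#'
#' @param rois ROI tibble.
#' @param path File path.
#' @return `write_roi_csv()` returns `path` invisibly; `read_roi_csv()` the
#'   ROI tibble.
#' @export
write_roi_csv <- function(rois, path) {
  utils::write.csv(rois, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_csv
#' @export
read_roi_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  req <- c("roi_id", "center_x_px", "center_y_px", "radius_px", "kind")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    abort(sprintf("ROI CSV is missing column(s): %s.", paste(missing, collapse = ", ")))
  }
  df$roi_id <- as.character(df$roi_id)
  df
}

# 16-bit scale used for TIFF serialization of arbitrary-unit intensities.
.tiff_scale <- 65535

#' Read and write multi-channel images as multi-page TIFF
#'
#' Channels are stored as pages of a 16-bit TIFF (values are clamped to
#' `[0, 65535]` and quantized); channel names travel in a plain-text
#' `<path>.channels` sidecar, since baseline TIFF writers do not carry
#' per-file channel metadata.
#'
#' @param image Numeric array `height x width x channels` with channel names
#'   in `dimnames(image)[[3]]`.
#' @param path File path.
#' @return `write_image_tiff()` returns `path` invisibly;
#'   `read_image_tiff()` the array (quantized to integer intensity units).
#' @export
write_image_tiff <- function(image, path) {
  if (!is.array(image) || length(dim(image)) != 3) {
    abort("`image` must be a height x width x channels array.")
  }
  ch <- dimnames(image)[[3]] %||% sprintf("ch%d", seq_len(dim(image)[3]))
  pages <- lapply(seq_len(dim(image)[3]), function(k) {
    pmin(pmax(image[, , k], 0), .tiff_scale) / .tiff_scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  writeLines(ch, paste0(path, ".channels"))
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- simplify2array(lapply(pages, function(p) round(p * .tiff_scale)))
  sidecar <- paste0(path, ".channels")
  ch <- if (file.exists(sidecar)) readLines(sidecar) else sprintf("ch%d", seq_len(dim(arr)[3]))
  if (length(ch) == dim(arr)[3]) dimnames(arr) <- list(NULL, NULL, ch)
  arr
}

#' Write a single-channel image stack as multi-page TIFF
#'
#' Frames are stored as pages; [read_image_stack_tiff()] returns the
#' `height x width x frames` array expected by [extract_roi_traces()].
#'
#' @param stack Numeric array `height x width x frames`.
#' @param path File path.
#' @return `write_image_stack_tiff()` returns `path` invisibly;
#'   `read_image_stack_tiff()` the array.
#' @export
write_image_stack_tiff <- function(stack, path) {
  write_image_tiff(stack, path)
}

#' @rdname write_image_stack_tiff
#' @export
read_image_stack_tiff <- function(path) {
  arr <- read_image_tiff(path)
  dimnames(arr) <- NULL
  arr
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param truth A data frame or list of ground-truth records.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::fromJSON(path)
}
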