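#' Simulate a triple-labelled immunofluorescence field
#'
#' Renders one synthetic coverslip field with three channels — `th`
#' (tyrosine hydroxylase, the dopaminergic marker), `glycogen`, and `gs`
#' (glycogen synthase) — as disk-shaped cell bodies over a noisy background.
#'
#' The intensity model: per-cell GS expression is lognormal (cell-to-cell
#' sdlog10 `cell_sdlog10`, on top of a shared coverslip staining factor of
#' sdlog10 `coverslip_sdlog10`, together spanning roughly an order of
#' magnitude across cells); TH-positive cells express `th_scale` times more
#' GS; glycogen is `slope * GS + noise`, so glycogen tracks synthase
#' expression linearly and TH-positive cells store `th_scale` more glycogen.
#' Under the `da_sulpiride` condition the glycogen of TH-positive cells is
#' additionally scaled by `sulpiride_scale` (a 45.4% reduction), leaving GS
#' and TH-negative cells untouched.
#'
#' @param condition `"control"` or a preset name; only `"da_sulpiride"`
#'   changes the intensity model.
#' @param n_cells Number of cell bodies (>= 2; at least one TH-positive and
#'   one TH-negative cell are always placed).
#' @param frame_shape `c(height_px, width_px)` of the field.
#' @param seed Integer seed.
#' @param th_fraction Fraction of TH-positive cells.
#' @param cell_radius_px Cell body radius in pixels.
#' @param gs_mean Mean GS intensity of a TH-negative cell (arbitrary units).
#' @param cell_sdlog10,coverslip_sdlog10 Lognormal spreads (log10 scale).
#' @param slope,intercept Linear glycogen-on-GS model.
#' @param glyc_noise_cv Relative sd of per-cell glycogen noise around the
#'   line (0 = exact line).
#' @param th_scale Ground-truth TH+/TH- scaling (default 1.7).
#' @param sulpiride_scale Glycogen scaling of TH-positive cells under
#'   `da_sulpiride` (default 0.546).
#' @param background Mean background level (arbitrary units).
#' @param pixel_noise_sd Gaussian pixel noise sd (0 for exact images).
#'
#' @return An object of class `if_sim`: list with
#'   * `image` — numeric array `height x width x 3`, channels named
#'     `th`, `glycogen`, `gs`;
#'   * `rois` — tibble of signal ROIs (one per cell: `roi_id`, `center_x_px`,
#'     `center_y_px`, `radius_px`, `kind = "signal"`, `th_status`) plus
#'     background ROIs (`kind = "background"`);
#'   * `truth` — per-cell tibble of the true mean intensities and scalings.
#' @export
simulate_if_image <- function(condition = "control",
                              n_cells = 24,
                              frame_shape = c(256, 256),
                              seed = 1,
                              th_fraction = 0.5,
                              cell_radius_px = 8,
                              gs_mean = 300,
                              cell_sdlog10 = 0.15,
                              coverslip_sdlog10 = 0,
                              slope = 1,
                              intercept = 0,
                              glyc_noise_cv = 0.15,
                              th_scale = 1.7,
                              sulpiride_scale = 0.546,
                              background = 20,
                              pixel_noise_sd = 2) {
  if (n_cells < 2) abort("`n_cells` must be at least 2 (one TH+ and one TH- cell).")
  n_cells <- as.integer(n_cells)
  h <- frame_shape[1]
  w <- frame_shape[2]
  r <- cell_radius_px
  treat <- if (identical(condition, "da_sulpiride")) sulpiride_scale else 1

  # grid placement with jitter; reserve one grid slot for background ROIs
  pitch <- ceiling(2.6 * r)
  nx <- floor(w / pitch)
  ny <- floor(h / pitch)
  if (nx * ny < n_cells + 1) {
    abort(sprintf(
      "Frame %dx%d px is too small to place %d non-overlapping cells of radius %g px.",
      h, w, n_cells, r
    ))
  }

  out <- with_seed(derive_seed(seed, 404), {
    slots <- sample(nx * ny, n_cells + 1)
    cx <- ((slots - 1) %% nx) * pitch + pitch / 2 + runif(n_cells + 1, -r / 5, r / 5)
    cy <- ((slots - 1) %/% nx) * pitch + pitch / 2 + runif(n_cells + 1, -r / 5, r / 5)
    th_status <- rep("negative", n_cells)
    n_pos <- max(1, min(n_cells - 1, round(th_fraction * n_cells)))
    th_status[sample(n_cells, n_pos)] <- "positive"
    is_pos <- th_status == "positive"

    slip_gain <- 10^rnorm(1, 0, coverslip_sdlog10)
    gs_true <- gs_mean * slip_gain * 10^rnorm(n_cells, 0, cell_sdlog10) *
      ifelse(is_pos, th_scale, 1)
    glyc_true <- pmax(0, slope * gs_true + intercept * slip_gain +
      glyc_noise_cv * slope * gs_true * rnorm(n_cells)) *
      ifelse(is_pos, treat, 1)
    th_true <- slip_gain * ifelse(is_pos, 500 * 10^rnorm(n_cells, 0, 0.1), 50)

    img <- array(
      rnorm(h * w * 3, background, pixel_noise_sd),
      dim = c(h, w, 3), dimnames = list(NULL, NULL, c("th", "glycogen", "gs"))
    )
    xs <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    ys <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
    intens <- cbind(th_true, glyc_true, gs_true)
    for (i in seq_len(n_cells)) {
      disk <- (xs - cx[i])^2 + (ys - cy[i])^2 <= r^2
      for (ch in 1:3) {
        img[, , ch][disk] <- img[, , ch][disk] + intens[i, ch]
      }
    }
    list(img = img, cx = cx, cy = cy, th_status = th_status,
         gs_true = gs_true, glyc_true = glyc_true, th_true = th_true,
         slip_gain = slip_gain)
  })

  rois <- dplyr::bind_rows(
    tibble(
      roi_id = sprintf("cell_%02d", seq_len(n_cells)),
      center_x_px = out$cx[seq_len(n_cells)],
      center_y_px = out$cy[seq_len(n_cells)],
      radius_px = r,
      kind = "signal",
      th_status = out$th_status
    ),
    tibble(
      roi_id = "bg_01",
      center_x_px = out$cx[n_cells + 1],
      center_y_px = out$cy[n_cells + 1],
      radius_px = r,
      kind = "background",
      th_status = NA_character_
    )
  )
  truth <- tibble(
    roi_id = sprintf("cell_%02d", seq_len(n_cells)),
    th_status = out$th_status,
    gs_true = out$gs_true,
    glycogen_true = out$glyc_true,
    th_true = out$th_true,
    coverslip_gain = out$slip_gain,
    th_scale = th_scale,
    treatment_scale = if (identical(condition, "da_sulpiride")) sulpiride_scale else 1,
    condition = if (is.character(condition)) condition else "custom"
  )
  structure(list(image = out$img, rois = rois, truth = truth), class = "if_sim")
}

#' Simulate and quantify a multi-coverslip immunofluorescence experiment
#'
#' Generates `n_coverslips` fields with [simulate_if_image()] (coverslips
#' assigned round-robin to `n_cultures` culture batches, each adding a shared
#' staining gain), quantifies every field with [quantify_cells()], and
#' returns culture-normalized cell records ready for [glycogen_gs_relation()],
#' [th_ratio()] or [treatment_effect()].
#'
#' @param condition Passed to [simulate_if_image()].
#' @param n_coverslips,cells_per_coverslip,n_cultures Experiment layout.
#' @param seed Integer master seed.
#' @param coverslip_sdlog10 Per-coverslip staining spread (log10 sd).
#' @param ... Further arguments to [simulate_if_image()].
#' @return A list with `records` (culture-normalized [quantify_cells()]
#'   output) and `truth` (per-cell ground truth with coverslip/culture ids).
#' @export
simulate_if_coverslips <- function(condition = "control",
                                   n_coverslips = 16,
                                   cells_per_coverslip = 28,
                                   n_cultures = 4,
                                   seed = 1,
                                   coverslip_sdlog10 = 0.48,
                                   ...) {
  sims <- purrr::map(seq_len(n_coverslips), function(k) {
    sim <- simulate_if_image(
      condition,
      n_cells = cells_per_coverslip,
      seed = derive_seed(seed, 505, k),
      coverslip_sdlog10 = coverslip_sdlog10,
      ...
    )
    ids <- tibble(
      coverslip_id = sprintf("cs_%02d", k),
      culture_id = sprintf("culture_%d", (k - 1) %% n_cultures + 1)
    )
    rec <- quantify_cells(sim$image, sim$rois) |>
      dplyr::mutate(!!!ids, .after = "roi_id")
    truth <- dplyr::mutate(sim$truth, !!!ids, .after = "roi_id")
    list(rec = rec, truth = truth)
  })
  records <- normalize_by_culture(purrr::list_rbind(purrr::map(sims, "rec")))
  list(records = records, truth = purrr::list_rbind(purrr::map(sims, "truth")))
}
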