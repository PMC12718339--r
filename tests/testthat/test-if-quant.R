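test_that("identical cells give culture-normalized values of exactly 1", {
  img <- array(5, dim = c(64, 64, 2), dimnames = list(NULL, NULL, c("glycogen", "gs")))
  for (cx in c(16, 48)) {
    mask <- synendure:::disk_mask(64, 64, cx, 32, 6)
    img[, , 1][mask] <- 25
    img[, , 2][mask] <- 45
  }
  rois <- tibble::tibble(
    roi_id = c("c1", "c2", "bg"),
    center_x_px = c(16, 48, 32), center_y_px = c(32, 32, 8),
    radius_px = c(6, 6, 4), kind = c("signal", "signal", "background"),
    culture_id = "cult1"
  )
  rec <- quantify_cells(img, rois) |> normalize_by_culture()
  expect_equal(rec$glycogen, c(20, 20))
  expect_equal(rec$gs, c(40, 40))
  expect_equal(rec$glycogen_norm, c(1, 1))
  expect_equal(rec$gs_norm, c(1, 1))
})

test_that("culture normalization averages to 1 per channel and cancels gains", {
  sim <- simulate_if_coverslips("control", n_coverslips = 4, cells_per_coverslip = 12,
                                n_cultures = 2, seed = 3)
  rec <- sim$records
  means <- rec |>
    dplyr::group_by(culture_id) |>
    dplyr::summarise(dplyr::across(dplyr::ends_with("_norm"), mean))
  expect_true(all(abs(as.matrix(means[, -1]) - 1) < 1e-9))

  # per-culture global gain leaves normalized values unchanged
  gained <- rec
  gain <- ifelse(gained$culture_id == "culture_1", 3.7, 0.4)
  for (ch in c("th", "glycogen", "gs")) gained[[ch]] <- gained[[ch]] * gain
  gained <- normalize_by_culture(gained[, !grepl("_norm$", names(gained))])
  expect_equal(gained$glycogen_norm, rec$glycogen_norm)
  expect_equal(gained$gs_norm, rec$gs_norm)
})

test_that("known per-cell intensities are recovered exactly without noise", {
  sim <- simulate_if_image("control", n_cells = 8, seed = 4,
                           glyc_noise_cv = 0, pixel_noise_sd = 0)
  rec <- quantify_cells(sim$image, sim$rois)
  expect_equal(rec$gs, sim$truth$gs_true, tolerance = 1e-9)
  expect_equal(rec$glycogen, sim$truth$glycogen_true, tolerance = 1e-9)
  # slope 1, zero intercept, noise off: measured glycogen equals GS per cell
  expect_equal(rec$glycogen, rec$gs, tolerance = 1e-9)
})

test_that("missing channels are rejected by name", {
  sim <- simulate_if_image("control", n_cells = 4, seed = 1)
  expect_error(quantify_cells(sim$image, sim$rois, channels = c("th", "dapi")), "dapi")
})

test_that("the glycogen-GS relation is exact on exact lines and bins correctly", {
  rec <- tibble::tibble(
    gs_norm = seq(0.05, 2.95, length.out = 60),
    glycogen_norm = 0.3 + 0.9 * gs_norm
  )
  rel <- glycogen_gs_relation(rec)
  expect_equal(unname(coef(rel$model)), c(0.3, 0.9), tolerance = 1e-9)
  # GS values spanning [0, 3) with width 0.5 -> 6 bins
  expect_equal(nrow(rel$bins), 6)
  expect_equal(rel$bins$gs_bin_mid, seq(0.25, 2.75, by = 0.5))
  # bin means lie on the line
  expect_equal(rel$bins$glycogen_mean, 0.3 + 0.9 * rel$bins$gs_bin_mid, tolerance = 0.02)
  expect_false(any(rel$bins$flagged))

  gl <- suppressWarnings(glance(rel)) # summary.lm warns on an exact fit
  expect_equal(gl$slope, 0.9, tolerance = 1e-9)
  td <- suppressWarnings(tidy(rel))
  expect_equal(td$term[2], "gs_norm")
  expect_s3_class(autoplot(rel), "ggplot")

  expect_error(glycogen_gs_relation(rec[1:5, ]), "at least 10")
  expect_error(
    glycogen_gs_relation(tibble::tibble(gs_norm = rep(1, 12), glycogen_norm = rep(1, 12))),
    "Degenerate"
  )
})

test_that("binned means converge to the regression line as noise vanishes", {
  slope_err <- vapply(c(0.3, 0.05, 0), function(cv) {
    sim <- simulate_if_coverslips("control", n_coverslips = 4, cells_per_coverslip = 20,
                                  seed = 11, glyc_noise_cv = cv, pixel_noise_sd = 0)
    rel <- glycogen_gs_relation(sim$records)
    line <- coef(rel$model)[1] + coef(rel$model)[2] * rel$bins$gs_mean
    ok <- rel$bins$n >= 5
    sqrt(mean((rel$bins$glycogen_mean[ok] - line[ok])^2))
  }, numeric(1))
  expect_true(all(diff(slope_err) <= 1e-9))
  expect_lt(slope_err[3], 1e-6)
})

test_that("th_ratio computes per-coverslip ratios and handles missing classes", {
  rec <- tibble::tibble(
    coverslip_id = rep(c("a", "b"), each = 4),
    th_status = rep(c("positive", "positive", "negative", "negative"), 2),
    glycogen_norm = c(170, 170, 100, 100, 2, 2, 2, 2)
  )
  r <- th_ratio(rec)
  expect_equal(r$per_coverslip$ratio, c(1.7, 1))
  expect_equal(r$summary$mean, 1.35)

  # coverslip without a TH-negative cell is excluded with a warning
  rec2 <- dplyr::bind_rows(rec, tibble::tibble(
    coverslip_id = "c", th_status = "positive", glycogen_norm = 5
  ))
  expect_warning(r2 <- th_ratio(rec2), "excluded")
  expect_equal(nrow(r2$per_coverslip), 2)
  expect_equal(r2$n_excluded, 1)
  expect_equal(glance(r2)$n_coverslips, 2)
})

test_that("th_ratio is invariant to a glycogen-channel gain within coverslips", {
  sim <- simulate_if_coverslips("control", n_coverslips = 4, cells_per_coverslip = 16, seed = 6)
  base <- th_ratio(sim$records)
  scaled <- sim$records
  scaled$glycogen_norm <- scaled$glycogen_norm * 12.5
  expect_equal(th_ratio(scaled)$per_coverslip$ratio, base$per_coverslip$ratio)
})

test_that("treatment_effect reports percent reduction in the figure-legend style", {
  # treated mean 0.546 of control -> 45.4% reduction
  eff <- treatment_effect(rep(0.546, 10), rep(1, 10))
  expect_equal(eff$percent_reduction, 45.4)
  expect_equal(eff$direction, "reduction")

  # treated = control -> 0% change
  expect_equal(treatment_effect(rep(2, 5), rep(2, 5))$percent_reduction, 0)

  # treated twice the control -> -100% (an increase), sign reported
  eff2 <- treatment_effect(rep(4, 5), rep(2, 5))
  expect_equal(eff2$percent_reduction, -100)
  expect_equal(eff2$direction, "increase")

  expect_error(treatment_effect(numeric(0), 1), "non-empty")
  expect_error(treatment_effect(1, c(-2, 0)), "positive")
})

test_that("sulpiride images carry the ground-truth TH-positive glycogen reduction", {
  ctl <- simulate_if_image("control", n_cells = 30, seed = 21,
                           glyc_noise_cv = 0, pixel_noise_sd = 0)
  sul <- simulate_if_image("da_sulpiride", n_cells = 30, seed = 21,
                           glyc_noise_cv = 0, pixel_noise_sd = 0)
  # identical seed: same cells, TH-positive glycogen scaled by 0.546
  pos <- ctl$truth$th_status == "positive"
  expect_equal(sul$truth$glycogen_true[pos], 0.546 * ctl$truth$glycogen_true[pos])
  expect_equal(sul$truth$glycogen_true[!pos], ctl$truth$glycogen_true[!pos])

  rec_c <- quantify_cells(ctl$image, ctl$rois)
  rec_s <- quantify_cells(sul$image, sul$rois)
  eff <- treatment_effect(
    rec_s$glycogen[rec_s$th_status == "positive"],
    rec_c$glycogen[rec_c$th_status == "positive"]
  )
  expect_equal(eff$percent_reduction, 45.4, tolerance = 1e-6)
})

test_that("fields too small for the requested cells are rejected", {
  expect_error(simulate_if_image("control", n_cells = 100, frame_shape = c(64, 64)),
               "too small")
  expect_error(simulate_if_image("control", n_cells = 1), "at least 2")
})
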