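test_that("an empty scene yields empty ground truth and zero rasters", {
  p <- scene_params(target_cell_count = 0)
  sc <- generate_scene(p, effect_spec("null"), rng_seed = 1)
  expect_equal(nrow(sc$truth), 0)
  expect_true(all(sc$rasters$nuclear == 0))
  expect_true(all(sc$rasters$boundary == 0))
  expect_true(all(sc$rasters$mito == 0))
  expect_true(all(sc$labels$cells == 0))
})

test_that("content follows the coupling law exactly when scatter is off", {
  p <- exact_params(content_scale = 5, target_cell_count = 40)
  sc <- generate_scene(p, effect_spec("null"), rng_seed = 7)
  expect_equal(sc$truth$content_au, 5 * sc$truth$cell_area_px)
  # the rendered (noiseless) mito raster integrates to the same content
  for (k in seq_len(nrow(sc$truth))) {
    id <- sc$truth$cell_id[k]
    expect_equal(sum(sc$rasters$mito[sc$labels$cells == id]),
                 sc$truth$content_au[k], tolerance = 1e-8)
  }
  # every nucleus sits strictly inside its cell
  expect_true(all(sc$truth$nucleus_area_px > 0))
  expect_true(all(sc$truth$nucleus_area_px < sc$truth$cell_area_px))
  nz <- sc$labels$nuclei > 0
  expect_true(all(sc$labels$cells[nz] == sc$labels$nuclei[nz]))
})

test_that("rendering is the identity with all corruption off, and seeded", {
  p <- exact_params(target_cell_count = 30)
  sc <- generate_scene(p, rng_seed = 3)
  imgs <- render_channels(sc$rasters, p, rng_seed = 4)
  expect_equal(imgs$mito$pixels, sc$rasters$mito)
  expect_equal(imgs$nuclear$pixels, sc$rasters$nuclear)
  # determinism: same seed bit-identical, different seed differs
  p2 <- scene_params(target_cell_count = 30)
  sc2 <- generate_scene(p2, rng_seed = 3)
  a <- render_channels(sc2$rasters, p2, rng_seed = 11)
  b <- render_channels(sc2$rasters, p2, rng_seed = 11)
  d <- render_channels(sc2$rasters, p2, rng_seed = 12)
  expect_identical(a$mito$pixels, b$mito$pixels)
  expect_false(identical(a$mito$pixels, d$mito$pixels))
})

test_that("the illumination field spans exactly the declared dynamic range", {
  g <- illumination_field(128, 128, amplitude = 0.5)
  expect_equal(max(g) / min(g), 1.5, tolerance = 1e-12)
  # flat unit raster picks up the field before noise
  p <- exact_params(illumination_gradient_amplitude = 0.5)
  flat <- matrix(1, p$image_height_px, p$image_width_px)
  out <- render_channels(list(nuclear = flat, boundary = flat, mito = flat),
                         p, rng_seed = 1)
  expect_equal(max(out$mito$pixels) / min(out$mito$pixels), 1.5,
               tolerance = 1e-10)
})

test_that("log-log regression across null cells recovers the coupling exponent", {
  p <- scene_params()
  truth <- do.call(rbind, lapply(1:2, function(i)
    generate_scene(p, effect_spec("null"), rng_seed = 100 + i)$truth))
  expect_gte(nrow(truth), 200)
  slope <- coef(lm(log(content_au) ~ log(cell_area_px), data = truth))[2]
  expect_lt(abs(slope - p$content_area_exponent), 0.1)
})

test_that("proportional effects preserve the content/area ratio; mito_only scales content alone", {
  p <- scene_params()
  pull <- function(eff, seeds) do.call(rbind, lapply(seeds, function(s)
    generate_scene(p, eff, rng_seed = s)$truth))
  null_t <- pull(effect_spec("null"), 201:203)
  prop_t <- pull(effect_spec("proportional", content_multiplier = 1.5), 204:206)
  mito_t <- pull(effect_spec("mito_only", content_multiplier = 1.5), 207:209)
  ratio <- function(tt) tt$content_au / tt$cell_area_px
  # proportional: per-cell content/area ratio matches null within 3 SE
  se <- sqrt(var(ratio(null_t)) / nrow(null_t) + var(ratio(prop_t)) / nrow(prop_t))
  expect_lt(abs(mean(ratio(prop_t)) - mean(ratio(null_t))), 3 * se)
  # proportional cells are larger on average
  expect_gt(mean(prop_t$cell_area_px), 1.2 * mean(null_t$cell_area_px))
  # mito_only: mean content fold within 1.5 +/- 3 SE, areas unchanged
  fold <- mean(mito_t$content_au) / mean(null_t$content_au)
  se_f <- fold * sqrt(var(mito_t$content_au) / nrow(mito_t) / mean(mito_t$content_au)^2 +
                      var(null_t$content_au) / nrow(null_t) / mean(null_t$content_au)^2)
  expect_lt(abs(fold - 1.5), 3 * se_f)
  expect_lt(abs(mean(mito_t$cell_area_px) / mean(null_t$cell_area_px) - 1), 0.1)
})

test_that("plate generation counts images, plants toxicity, and is deterministic", {
  p <- scene_params(target_cell_count = 40)
  pm <- data.frame(plate = "P1", well = sprintf("A%02d", 1:4), day = 1,
                   role = "control", compound_id = "DMSO", dose_uM = 0)
  out <- generate_plate(pm, params = p, master_seed = 9)
  expect_length(out$images, 12)  # 3 channels x 4 wells
  expect_equal(nrow(out$truth_wells), 4)
  out2 <- generate_plate(pm, params = p, master_seed = 9)
  expect_identical(lapply(out$images, `[[`, "pixels"),
                   lapply(out2$images, `[[`, "pixels"))
  # toxic thinning: survival 0.2 of 130 targets ~26 cells
  ptox <- scene_params()
  pm_t <- data.frame(plate = "P1", well = sprintf("B%02d", 1:6), day = 1,
                     role = "treatment", compound_id = "TOX", dose_uM = 10)
  pm_t <- rbind(pm_t, data.frame(plate = "P1", well = "C01", day = 1,
                                 role = "control", compound_id = "DMSO",
                                 dose_uM = 0))
  eff <- list(TOX = effect_spec("toxic", survival_fraction = 0.2))
  tout <- generate_plate(pm_t, eff, params = ptox, master_seed = 2,
                         keep_images = FALSE)
  counts <- tout$truth_wells$n_cells_true[tout$truth_wells$compound_id == "TOX"]
  expect_lt(abs(mean(counts) - 26), 12)  # ~5 sd of the mean of 6 binomials
  expect_true(all(counts < 40))
})

test_that("plate generation validates its inputs", {
  pm <- data.frame(plate = "P1", well = c("A01", "A01"), day = 1,
                   role = "control", compound_id = "DMSO", dose_uM = 0)
  expect_error(generate_plate(pm), "duplicated")
  pm2 <- data.frame(plate = "P1", well = c("A01", "A02"), day = 1,
                    role = c("control", "treatment"),
                    compound_id = c("DMSO", "XYZ"), dose_uM = 0)
  expect_error(generate_plate(pm2), "XYZ")
  pm3 <- data.frame(plate = "P1", well = "A01", day = 1,
                    role = "treatment", compound_id = "C1", dose_uM = 0)
  expect_error(generate_plate(pm3, list(C1 = effect_spec("null"))),
               "no control wells")
})

test_that("impossible packing fails loudly, naming the achieved count", {
  p <- scene_params(image_height_px = 64, image_width_px = 64,
                    target_cell_count = 500)
  expect_error(generate_scene(p, rng_seed = 1), "impossible packing")
})

test_that("the statistical fast path matches the rendered generator's moments", {
  p <- scene_params()
  recs <- do.call(rbind, lapply(1:6, function(i)
    simulate_cell_records(p, effect_spec("null"), rng_seed = 300 + i)))
  truth <- do.call(rbind, lapply(1:3, function(i)
    generate_scene(p, effect_spec("null"), rng_seed = 400 + i)$truth))
  expect_equal(nrow(recs), 6 * p$target_cell_count)
  # mean cell area and mean measured content agree within ~10%
  expect_lt(abs(mean(recs$cell_area_px) / mean(truth$cell_area_px) - 1), 0.1)
  expect_lt(abs(mean(recs$integrated_mito_intensity_au) /
                ((1 - p$nuclear_bleed_fraction) * mean(truth$content_au)) - 1), 0.1)
})
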