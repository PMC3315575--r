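fake_records <- function(norm_values) {
  n <- length(norm_values)
  data.frame(cell_id = seq_len(n), nucleus_area_px = rep(50, n),
             cell_area_px = rep(400, n), cytoplasm_area_px = rep(350, n),
             integrated_mito_intensity_au = norm_values * 350,
             normalized_mito_intensity_au_per_px = norm_values,
             touches_border = rep(FALSE, n))
}

fake_summaries <- function(values, day = 1, prefix = "W", compound = NULL,
                           count = 100, area = NULL) {
  # default areas vary slightly so the area metric is never degenerate
  if (is.null(area)) area <- 350 + seq_along(values)
  out <- data.frame(plate = "P", well = sprintf("%s%02d", prefix, seq_along(values)),
                    day = day, cell_count = count,
                    median_cyto_area_px = area,
                    median_integrated_mito_au = values * 350,
                    median_normalized_mito_au_per_px = values)
  if (!is.null(compound)) out$compound_id <- compound
  out
}

test_that("well summaries take medians over included cells", {
  s <- summarize_well(fake_records(c(1, 2, 9)))
  expect_equal(s$median_normalized_mito_au_per_px, 2)
  expect_equal(s$cell_count, 3)
  one <- summarize_well(fake_records(7))
  expect_equal(one$median_normalized_mito_au_per_px, 7)
  expect_equal(one$median_cyto_area_px, 350)
  empty <- summarize_well(fake_records(numeric(0)))
  expect_equal(empty$cell_count, 0)
  expect_true(is.na(empty$median_normalized_mito_au_per_px))
  # against an independent sort-based median on many records
  set.seed(1)
  v <- rlnorm(200)
  expect_equal(summarize_well(fake_records(v))$median_normalized_mito_au_per_px,
               oracle_median(v))
})

test_that("control fits use the declared estimators and reject degeneracy", {
  mom <- fit_controls(fake_summaries(c(90, 100, 110) / 350), estimator = "moment")
  raw <- mom[mom$metric == "raw", ]
  expect_equal(raw$location, 100)
  expect_equal(raw$scale, 10)
  rob <- fit_controls(fake_summaries(c(1, 2, 3, 4, 100)), estimator = "robust")
  nrm <- rob[rob$metric == "norm", ]
  expect_equal(nrm$location, 3)
  expect_equal(nrm$scale, 1.4826)
  expect_error(fit_controls(fake_summaries(c(10, 10, 10, 10))), "degenerate")
  expect_error(fit_controls(fake_summaries(c(1, 2), day = 5)), "day 5")
})

test_that("z-scores center, scale and are scale-equivariant", {
  ctrl <- fit_controls(fake_summaries(c(90, 100, 110) / 350),
                       estimator = "moment")
  s <- fake_summaries(120 / 350, prefix = "T")
  z <- well_z(s, ctrl)
  expect_equal(z$z_raw, 2.0)
  s0 <- fake_summaries(100 / 350, prefix = "T")
  expect_equal(well_z(s0, ctrl)$z_raw, 0)
  # multiplying all values and the control distribution by k leaves z fixed
  k <- 13.7
  ctrl_k <- ctrl
  ctrl_k$location <- ctrl$location * k
  ctrl_k$scale <- ctrl$scale * k
  s_k <- s
  for (col in c("median_cyto_area_px", "median_integrated_mito_au",
                "median_normalized_mito_au_per_px"))
    s_k[[col]] <- s[[col]] * k
  expect_equal(well_z(s_k, ctrl_k)$z_raw, z$z_raw)
  # empty well -> missing z
  e <- fake_summaries(NA_real_, prefix = "E", count = 0)
  expect_true(is.na(well_z(e, ctrl)$z_raw))
})

test_that("Stouffer composite reduces to z for n = 1 and is null-calibrated", {
  expect_equal(composite_z(2.3), 2.3)
  expect_equal(composite_z(c(2, 3)), 5 / sqrt(2))
  expect_true(is.na(composite_z(numeric(0))))
  expect_equal(composite_z(c(1, NA, 3)), 4 / sqrt(2))
  set.seed(99)
  comp <- replicate(1e4, composite_z(rnorm(2)))
  expect_lt(abs(var(comp) - 1), 0.05)
})

test_that("toxicity filter applies the strict 40-cell rule", {
  expect_false(toxicity_filter(39))
  expect_true(toxicity_filter(40))
  expect_false(toxicity_filter(0))
  expect_equal(toxicity_filter(c(10, 40, 200)), c(FALSE, TRUE, TRUE))
  # synthetic toxic wells (survival 0.2 of 130) virtually always fail it
  p <- scene_params()
  eff <- effect_spec("toxic", survival_fraction = 0.2)
  counts <- vapply(1:300, function(i)
    nrow(simulate_cell_records(p, eff, rng_seed = 5000 + i)), integer(1))
  expect_gte(mean(counts < 40), 0.99)
})

test_that("hit calling is strict at the threshold", {
  sc <- data.frame(compound_id = c("a", "b", "c"),
                   passed_toxicity = c(TRUE, TRUE, FALSE),
                   composite_z_norm = c(1.99, 1.98, 5))
  hits <- call_hits(sc, "norm", 1.98)
  expect_equal(hits$compound_id, "a")   # 1.98 itself is not a hit; toxic never
  expect_equal(nrow(call_hits(sc[0, ], "norm")), 0)
})

test_that("fold changes are ratios to same-day control means, averaged over replicates", {
  ctrl <- fake_summaries(rep(100 / 350, 4), area = c(340, 360, 345, 355))
  trt <- rbind(fake_summaries(150 / 350, prefix = "T", compound = "cmp1",
                              area = 350),
               fake_summaries(130 / 350, prefix = "U", compound = "cmp1",
                              area = 350))
  fc <- fold_changes(trt, ctrl)
  expect_equal(fc$fold_change_mito, 1.4)  # mean of 1.5 and 1.3
  expect_equal(fc$fold_change_area, 1.0)
  same <- fold_changes(fake_summaries(100 / 350, prefix = "T", compound = "x",
                                      area = 350), ctrl)
  expect_equal(c(same$fold_change_mito, same$fold_change_area), c(1, 1))
  zero <- fake_summaries(rep(0, 3))
  expect_error(fold_changes(trt, zero), "zero control mean")
})

test_that("effect classification separates proportional from dissociated", {
  expect_equal(classify_effect(5, 5, 0.2), "proportional")
  expect_equal(classify_effect(4, 0.3, 4), "dissociated_up")
  expect_equal(classify_effect(-1, 0.3, -4), "dissociated_down")
  expect_equal(classify_effect(0, 0, 0), "none")
  expect_equal(classify_effect(5, 0.5, 0.2), "none")  # raw up, area flat, norm flat
  expect_equal(classify_effect(c(5, 4), c(5, 0.3), c(0.2, 4)),
               c("proportional", "dissociated_up"))
})

test_that("expected normalized z grows monotonically with the planted content multiplier", {
  p <- scene_params()
  mean_z <- vapply(c(1, 1.2, 1.5, 2), function(m) {
    eff <- if (m == 1) effect_spec("null") else
      effect_spec("mito_only", content_multiplier = m)
    ctrl <- do.call(rbind, lapply(1:12, function(i) {
      r <- simulate_cell_records(p, effect_spec("null"), rng_seed = 7000 + i)
      summarize_well(r, "P", sprintf("C%02d", i), 1)
    }))
    fit <- fit_controls(ctrl)
    trt <- do.call(rbind, lapply(1:6, function(i) {
      r <- simulate_cell_records(p, eff, rng_seed = 8000 + 100 * round(m * 10) + i)
      summarize_well(r, "P", sprintf("T%02d", i), 1)
    }))
    mean(well_z(trt, fit)$z_norm)
  }, numeric(1))
  expect_true(all(diff(mean_z) > 0))
})
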