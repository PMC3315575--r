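two_cell_field <- function() {
  # cell 1 interior, cell 2 touching the left border
  cells <- matrix(0L, 40, 40)
  cells[disk_mask(40, 40, 20, 25, 9)] <- 1L
  cells[15:25, 1:6] <- 2L
  nuc <- matrix(0L, 40, 40)
  nuc[disk_mask(40, 40, 20, 25, 4)] <- 1L
  nuc[18:22, 2:4] <- 2L
  list(cells = cells, nuclei = nuc, cyto = cytoplasm_mask(cells, nuc))
}

test_that("a zero mito channel integrates to zero everywhere", {
  f <- two_cell_field()
  rec <- measure_cells(f$cyto, f$cells, f$nuclei, matrix(0, 40, 40),
                       background_cutoff = 0, exclude_border = FALSE)
  expect_equal(rec$integrated_mito_intensity_au, c(0, 0))
})

test_that("masking-mode arithmetic: uniform cytoplasm intensity above cutoff", {
  cells <- matrix(0L, 30, 30)
  cells[5:24, 5:24] <- 1L
  nuc <- matrix(0L, 30, 30)
  nuc[10:19, 10:19] <- 1L   # 100 px nucleus
  cyto <- cytoplasm_mask(cells, nuc)
  stopifnot(sum(cyto == 1L) == 300)
  I <- matrix(0, 30, 30)
  I[cells == 1L] <- 5       # every px is 5, cutoff 2 -> full intensity kept
  rec <- measure_cells(cyto, cells, nuc, I, background_cutoff = 2,
                       exclude_border = FALSE)
  expect_equal(rec$integrated_mito_intensity_au, 5 * 300)
  expect_equal(rec$normalized_mito_intensity_au_per_px, 5)
  # subtraction mode subtracts the cutoff instead
  rec2 <- measure_cells(cyto, cells, nuc, I, background_cutoff = 2,
                        exclude_border = FALSE, background = "subtract")
  expect_equal(rec2$integrated_mito_intensity_au, 3 * 300)
  # masking mode zeroes sub-cutoff pixels entirely
  I[cells == 1L] <- 1.5
  rec3 <- measure_cells(cyto, cells, nuc, I, background_cutoff = 2,
                        exclude_border = FALSE)
  expect_equal(rec3$integrated_mito_intensity_au, 0)
})

test_that("border cells are flagged and excluded by default", {
  f <- two_cell_field()
  I <- matrix(10, 40, 40)
  all_rec <- measure_cells(f$cyto, f$cells, f$nuclei, I, exclude_border = FALSE)
  expect_equal(nrow(all_rec), 2)
  expect_equal(all_rec$touches_border, c(FALSE, TRUE))
  kept <- measure_cells(f$cyto, f$cells, f$nuclei, I, exclude_border = TRUE)
  expect_equal(kept$cell_id, 1L)
  # cytoplasm_area = cell_area - nucleus_area for every record
  expect_equal(all_rec$cytoplasm_area_px,
               all_rec$cell_area_px - all_rec$nucleus_area_px)
})

test_that("mitochondrial area fraction is exact, NA on empty cytoplasm, and relabel-invariant", {
  cyto <- matrix(0L, 20, 20)
  cyto[1:10, 1:10] <- 4L  # 100 px
  fg <- matrix(FALSE, 20, 20)
  expect_equal(mito_area_fraction(fg, cyto)$per_label$fraction, 0)
  fg[1:5, 1:5] <- TRUE    # 25 px inside
  res <- mito_area_fraction(fg, cyto)
  expect_equal(res$per_label$fraction, 0.25)
  expect_equal(res$overall, 0.25)
  # relabeling leaves fractions unchanged
  cyto2 <- cyto; cyto2[cyto == 4L] <- 9L
  expect_equal(mito_area_fraction(fg, cyto2)$per_label$fraction, 0.25)
  # label with no cytoplasm pixels is absent; empty mask overall is NA
  none <- matrix(0L, 20, 20)
  expect_true(is.na(mito_area_fraction(fg, none)$overall))
})

test_that("segmentation matching scores ground truth recovery", {
  truth <- matrix(0L, 30, 30)
  truth[1:15, 1:15] <- 1L; truth[16:30, 16:30] <- 2L
  pred <- truth  # perfect
  m <- match_segmentation(truth, pred)
  expect_equal(m$recall, 1)
  expect_equal(nrow(m$matches), 2)
  shifted <- matrix(0L, 30, 30)
  shifted[1:15, 3:17] <- 7L  # IoU 13/17 with cell 1 > 0.7
  m2 <- match_segmentation(truth, shifted, iou_min = 0.7)
  expect_equal(m2$matches$truth, 1L)
  expect_equal(m2$recall, 0.5)
})
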