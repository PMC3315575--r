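test_that("nuclei segmentation handles blank, separated and touching disks", {
  blank <- channel_image(matrix(0, 64, 64), channel = "nuclear")
  expect_equal(sum(segment_nuclei(blank)), 0)

  # five well-separated disks
  img <- matrix(50, 96, 96)
  centers <- cbind(r = c(20, 20, 48, 76, 76), c = c(20, 70, 48, 20, 70))
  for (k in 1:5) img[disk_mask(96, 96, centers[k, 1], centers[k, 2], 7)] <- 4000
  lab <- segment_nuclei(channel_image(img, channel = "nuclear"))
  ids <- setdiff(unique(as.vector(lab)), 0)
  expect_length(ids, 5)
  for (k in 1:5) {
    id <- lab[centers[k, 1], centers[k, 2]]
    expect_gt(id, 0)
    sel <- which(lab == id, arr.ind = TRUE)
    expect_lt(abs(mean(sel[, 1]) - centers[k, 1]), 1)
    expect_lt(abs(mean(sel[, 2]) - centers[k, 2]), 1)
  }

  # two overlapping disks, centers 1.5 radii apart, are declumped
  img2 <- matrix(50, 64, 64)
  img2[disk_mask(64, 64, 32, 26, 8)] <- 4000
  img2[disk_mask(64, 64, 32, 38, 8)] <- 4000
  lab2 <- segment_nuclei(channel_image(img2, channel = "nuclear"))
  expect_length(setdiff(unique(as.vector(lab2)), 0), 2)
})

test_that("a single seed floods the reachable foreground; no seeds warn", {
  I <- matrix(0.5, 32, 32)
  seeds <- matrix(0L, 32, 32); seeds[16, 16] <- 3L
  lab <- propagate_cells(I, seeds, lambda = 0.1, normalize = FALSE)
  expect_true(all(lab == 3L))
  empty <- matrix(0L, 32, 32)
  expect_warning(z <- propagate_cells(I, empty, normalize = FALSE), "no seeds")
  expect_true(all(z == 0L))
})

test_that("uniform images partition by grid geodesic distance with label ties", {
  I <- matrix(0.2, 48, 48)
  seeds <- matrix(0L, 48, 48)
  seeds[24, 12] <- 1L; seeds[24, 36] <- 2L
  lab <- propagate_cells(I, seeds, lambda = 0.7, normalize = FALSE)
  d1 <- octile_dist(48, 48, 24, 12)
  d2 <- octile_dist(48, 48, 24, 36)
  expected <- ifelse(d1 < d2, 1L, ifelse(d2 < d1, 2L, 1L))  # ties -> label 1
  expect_identical(as.vector(lab), as.vector(expected))
})

test_that("large lambda converges to the nearest-seed spatial partition", {
  set.seed(8)
  I <- matrix(runif(48 * 48), 48, 48)  # arbitrary intensities
  seeds <- matrix(0L, 48, 48)
  seeds[10, 10] <- 1L; seeds[40, 35] <- 2L; seeds[12, 40] <- 3L
  lab <- propagate_cells(I, seeds, lambda = 1e8, normalize = FALSE)
  d <- vapply(list(c(10, 10), c(40, 35), c(12, 40)),
              function(p) as.vector(octile_dist(48, 48, p[1], p[2])),
              numeric(48 * 48))
  expected <- max.col(-d, ties.method = "first")
  # at exact geodesic ties the vanishing intensity term decides; compare only
  # clearly-decided pixels
  gap <- apply(d, 1, function(v) diff(sort(v))[1])
  decided <- gap > 1e-6
  expect_gt(mean(decided), 0.95)
  expect_identical(as.vector(lab)[decided], as.integer(expected)[decided])
})

test_that("propagation matches an independent Dijkstra oracle on random images", {
  set.seed(31)
  for (rep in 1:4) {
    I <- matrix(runif(40 * 40), 40, 40)
    seeds <- matrix(0L, 40, 40)
    seeds[sample(40 * 40, 3)] <- 1:3
    for (lam in c(0, 0.05, 10)) {
      imp <- propagate_cells(I, seeds, lambda = lam, normalize = FALSE)
      expect_identical(imp, oracle_propagate(I, seeds, lam))
    }
  }
})

test_that("propagation validates its inputs", {
  I <- matrix(0.5, 16, 16)
  seeds <- matrix(0L, 16, 16); seeds[4, 4] <- 1L
  fg <- matrix(TRUE, 16, 16); fg[4, 4] <- FALSE
  expect_error(propagate_cells(I, seeds, foreground = fg), "foreground")
  expect_error(propagate_cells(I, seeds, lambda = -1), "lambda")
  expect_error(propagate_cells(I, matrix(0L, 8, 8)), "dimensions")
})

test_that("cytoplasm masking subtracts nuclei and enforces containment", {
  cells <- matrix(0L, 40, 40)
  cells[disk_mask(40, 40, 20, 20, 10)] <- 5L   # 317 px disk
  nuc <- matrix(0L, 40, 40)
  nuc[disk_mask(40, 40, 20, 20, 5)] <- 5L      # 81 px disk
  expect_equal(sum(cells == 5L), 317)
  expect_equal(sum(nuc == 5L), 81)
  cyto <- cytoplasm_mask(cells, nuc)
  expect_equal(sum(cyto == 5L), 236)
  expect_true(all(cyto[nuc > 0] == 0))
  # nucleus == cell -> empty cytoplasm
  cyto2 <- cytoplasm_mask(nuc, nuc)
  expect_equal(sum(cyto2), 0)
  # nucleus spanning two cells fails naming the label
  cells2 <- cells
  cells2[, 1:20] <- ifelse(cells[, 1:20] > 0, 9L, 0L)
  expect_error(cytoplasm_mask(cells2, nuc), "span")
})

test_that("pixel bookkeeping is conserved on generated scenes", {
  p <- scene_params(target_cell_count = 60)
  sc <- generate_scene(p, rng_seed = 21)
  cyto <- cytoplasm_mask(sc$labels$cells, sc$labels$nuclei)
  ids <- sc$truth$cell_id
  nb <- max(ids)
  expect_equal(tabulate(cyto, nb)[ids] + tabulate(sc$labels$nuclei, nb)[ids],
               tabulate(sc$labels$cells, nb)[ids])
  nz <- sc$labels$nuclei > 0
  expect_true(all(sc$labels$cells[nz] == sc$labels$nuclei[nz]))
})
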