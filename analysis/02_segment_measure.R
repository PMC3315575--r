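#!/usr/bin/env Rscript
# Per-image analysis of the demonstration plate written by 01_simulate_plate.R:
# illumination correction from the plate's own images, nuclei segmentation,
# propagation of cell boundaries, nucleus masking, and per-cell measurement.
# Writes the per-cell table and reports segmentation quality against the
# generator's ground-truth masks.

library(mitoscreen)

in_dir <- "results/plate_demo"
master_seed <- 20260924L
if (!file.exists(file.path(in_dir, "platemap.csv")))
  stop("run analysis/01_simulate_plate.R first")

platemap <- read.csv(file.path(in_dir, "platemap.csv"))
params <- scene_params()

channels <- c("nuclear", "boundary", "mito")
imgs <- list()
for (i in seq_len(nrow(platemap))) {
  rw <- platemap[i, ]
  for (ch in channels)
    imgs[[paste(rw$plate, rw$well, 1, ch, sep = "_")]] <-
      read_channel_image(in_dir, rw$plate, rw$well, 1, ch, day = rw$day)
}

profiles <- lapply(setNames(nm = channels), function(ch)
  estimate_illumination(Filter(function(im) im$channel == ch, imgs)))

cells <- list(); recalls <- numeric(0)
effects <- list(
  PROP = effect_spec("proportional", content_multiplier = 1.5),
  MITO = effect_spec("mito_only", content_multiplier = 1.5),
  DOWN = effect_spec("mito_down", content_multiplier = 0.6),
  TOX  = effect_spec("toxic", survival_fraction = 0.2))
for (i in seq_len(nrow(platemap))) {
  rw <- platemap[i, ]
  corrected <- lapply(setNames(nm = channels), function(ch)
    correct_illumination(imgs[[paste(rw$plate, rw$well, 1, ch, sep = "_")]],
                         profiles[[ch]]))
  sw <- segment_well(corrected)
  rec <- sw$records
  if (nrow(rec) > 0) {
    rec$plate <- rw$plate; rec$well <- rw$well; rec$day <- rw$day
    cells[[length(cells) + 1L]] <- rec
  }
  # ground truth masks are reproducible from the master seed
  eff <- if (rw$role == "control") effect_spec("null") else effects[[rw$compound_id]]
  sc <- generate_scene(params, eff,
                       rng_seed = mitoscreen:::derive_seed(master_seed, "scene",
                                                           rw$plate, rw$well))
  if (nrow(sc$truth) > 0) {
    r <- match_segmentation(sc$labels$cells, sw$cells, 0.7)$recall
    recalls <- c(recalls, setNames(r, rw$compound_id))
  }
}
cell_table <- do.call(rbind, cells)
write.csv(cell_table, file.path(in_dir, "cells.csv"), row.names = FALSE)

confl <- recalls[names(recalls) != "TOX"]
cat(sprintf("Measured %d cells across %d wells -> %s\n",
            nrow(cell_table), nrow(platemap), file.path(in_dir, "cells.csv")))
cat(sprintf("Segmentation on confluent wells: %.1f%% of ground-truth cells matched 1-1 at IoU >= 0.7 (range %.2f-%.2f).\n",
            100 * mean(confl), min(confl), max(confl)))
cat(sprintf("Toxic well recall is %.2f by construction: propagation tiles the dead-cell gaps\nonto the surviving seeds; its %d measured cells fall below the 40-cell filter, so it\nnever reaches scoring.\n",
            recalls[["TOX"]],
            sum(cell_table$well == "B04")))
cat(sprintf("Illumination profiles estimated per channel from %d images each.\n",
            nrow(platemap)))
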