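#!/usr/bin/env Rscript
# Simulate a small demonstration plate of synthetic monolayer images.
#
# Twelve wells on one plate: eight DMSO controls and four treatment wells
# carrying the canonical planted effects (proportional 1.5x, mito-only 1.5x,
# mito-down 0.6x, toxic at 20% survival). Images are written as 16-bit TIFFs
# with the per-cell and per-well ground truth alongside, so the downstream
# scripts can be run against files on disk exactly as a real screen would be.

library(mitoscreen)

out_dir <- "results/plate_demo"
master_seed <- 20260924L

params <- scene_params()
effects <- list(
  PROP = effect_spec("proportional", content_multiplier = 1.5),
  MITO = effect_spec("mito_only", content_multiplier = 1.5),
  DOWN = effect_spec("mito_down", content_multiplier = 0.6),
  TOX  = effect_spec("toxic", survival_fraction = 0.2))

platemap <- rbind(
  data.frame(plate = "DEMO", well = sprintf("A%02d", 1:8), day = 1,
             role = "control", compound_id = "DMSO", dose_uM = 0),
  data.frame(plate = "DEMO", well = sprintf("B%02d", 1:4), day = 1,
             role = "treatment", compound_id = names(effects), dose_uM = 10))

plate <- generate_plate(platemap, effects, params, master_seed = master_seed,
                        out_dir = out_dir, keep_images = FALSE)

cat(sprintf("Wrote %d channel images for %d wells to %s\n",
            3 * nrow(platemap), nrow(platemap), out_dir))
tw <- plate$truth_wells
cat("\nPlanted ground truth per well:\n")
print(tw[, c("well", "compound_id", "effect_class", "n_cells_true")],
      row.names = FALSE)
cat(sprintf("\nControl wells average %.0f cells; the toxic well has %d (below the 40-cell filter).\n",
            mean(tw$n_cells_true[tw$role == "control"]),
            tw$n_cells_true[tw$compound_id == "TOX"]))
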