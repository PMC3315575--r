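# mitoscreen

High-content screens can measure, cell by cell, how much mitochondrial
signal a compound induces — but mitochondrial content and cell size are
tightly coupled, so most compounds that raise total per-cell mitochondrial
intensity turn out simply to have made cells bigger. The scientifically
interesting compounds are the rare ones that *dissociate* content from
size. `mitoscreen` implements the complete computational side of such a
screen for confluent endothelial-like monolayers, together with a
ground-truthed synthetic image generator, so that every stage is testable
without any microscope data. It is aimed at computational biologists who
want a fully reproducible, quantitatively validated reference
implementation of this class of pipeline.

## What it computes

**Per image** (one site per well; nuclear, cell-boundary and mitochondrial
channels):

* retrospective illumination correction per plate and channel (smoothed
  unit-mean mean image);
* mitochondrial background cutoff by **three-class Otsu**: the threshold
  pair (t_low, t_high) maximising the between-class variance over three
  intensity classes, middle class assigned to foreground;
* nuclei by Otsu + watershed declumping on the distance transform;
* cell boundaries by **seeded propagation** (multi-source Dijkstra, C++):
  a step from pixel *p* to neighbour *q* costs
  `sqrt(lambda * s^2 + (I(p) - I(q))^2)`, so boundaries follow the bright
  cortical-actin ridges between cells, with spatial regularization lambda;
* cytoplasm = cell minus nucleus; per cell: areas (px²), integrated
  mitochondrial intensity over the cytoplasm, and that total normalized to
  cytoplasm area. Border-touching cells are excluded.

**Per screen:** per-image medians; robust (median/MAD) control
distributions per screening day from DMSO control plates; z-scores of
treated wells against day-matched controls; **Stouffer composite**
`sum(z)/sqrt(n)` across biological duplicates; exclusion of wells with
fewer than 40 cells; hits at composite z > 1.98 on the size-normalized
metric; fold changes versus control means; and classification of each
compound as `proportional`, `dissociated_up`, `dissociated_down` or `none`.

**Secondary-assay calculators:** mtDNA/nuDNA copy-number ratio
`2^(Ct_nuclear - Ct_mito)`, delta-delta-Ct expression folds
`2^(-ddCt)`, and respiration fold-changes under alternative normalizations
(cell count, cell volume, total protein, none).

**Synthetic data:** `generate_scene()`/`generate_plate()` build confluent
monolayers as weighted Voronoi tilings of Poisson-disk centers, with
per-cell mitochondrial content coupled to cell area by a configurable power
law, clumped mitochondrial texture with nuclear bleed, planted compound
effects (proportional / mito-only / mito-down / toxic), multiplicative
illumination gradients, blur and Poisson-Gaussian noise — everything
seeded and byte-reproducible, with full ground truth.

## Worked example

Segment one synthetic field carrying a 1.5x mito-only effect:

```r
library(mitoscreen)
params <- scene_params()
scene  <- generate_scene(params, effect_spec("mito_only", content_multiplier = 1.5),
                         rng_seed = 7)
imgs   <- render_channels(scene$rasters, params, rng_seed = 8)
seg    <- segment_well(imgs)
match_segmentation(scene$labels$cells, seg$cells, iou_min = 0.7)$recall
```

```
cells found: 130 | true: 130
matched at IoU>=0.7: 124 (recall 0.95)
```

All 130 cells are recovered, 124 of them with IoU ≥ 0.7 against the ground
truth mask; `seg$records` holds one row per interior cell with its
cytoplasm area and (nucleus-masked, background-thresholded) mitochondrial
intensities.

Score a small duplicate screen with planted effects (20 inert compounds,
one mito-only 1.5x, one proportional 1.5x, one toxic at 20% survival;
DMSO control plates on both screening days):

```r
ids <- c(sprintf("INERT%02d", 1:20), "MITO01", "PROP01", "TOX01")
effects <- c(setNames(replicate(20, effect_spec("null"), simplify = FALSE), ids[1:20]),
             list(MITO01 = effect_spec("mito_only", content_multiplier = 1.5),
                  PROP01 = effect_spec("proportional", content_multiplier = 1.5),
                  TOX01  = effect_spec("toxic", survival_fraction = 0.2)))
pm  <- generate_platemap(ids, n_days = 2, wells_per_plate = 48)
cfg <- screen_config(pm, effects, params = scene_params(),
                     master_seed = 11, measure = "truth")
res <- run_screen(cfg)
```

```
 compound_id composite_z_raw composite_z_area composite_z_norm passed_toxicity
     INERT01           0.356           -0.372            0.119            TRUE
      MITO01           9.642            0.164           17.083            TRUE
      PROP01          11.069           15.836            1.875            TRUE
       TOX01              NA               NA               NA           FALSE
 is_hit   effect_class fold_change_mito fold_change_area
  FALSE           none             1.02            0.989
   TRUE dissociated_up             1.48            0.995
  FALSE           none             1.55            1.433
  FALSE           <NA>               NA               NA
```

Reading this: the mito-only compound raises total mitochondrial intensity
(z_raw ≈ 9.6) *without* raising cell area (z_area ≈ 0.16), so its
size-normalized score is enormous (z_norm ≈ 17) — a hit, classed
`dissociated_up`, with folds (1.48, 1.00). The proportional compound raises
content and area together (folds 1.55 and 1.43), so its normalized score
stays near the null band and it is not a hit. The toxic well falls under
the 40-cell filter and never reaches scoring. One inert compound also
crosses z > 1.98 — the expected ~2% false-positive rate at this threshold.

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
package's analyses end to end, writing tables and figures under `results/`:

1. `01_simulate_plate.R` — simulate a 12-well demonstration plate to TIFF +
   ground-truth CSV;
2. `02_segment_measure.R` — read those images back, correct, segment,
   measure, and score segmentation quality against ground truth;
3. `03_screen_statistics.R` — a full 368-compound duplicate screen with
   planted effects: scores, hits, classification table, fold-change scatter
   and composite-z histograms;
4. `04_secondary_assays.R` — copy-number ratios, expression folds and
   respiration folds on synthetic assay tables.

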