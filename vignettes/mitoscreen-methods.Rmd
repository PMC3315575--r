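---
title: "Methods: simulating and scoring a mitochondrial-content screen"
author: "mitoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring a mitochondrial-content screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The assay being modelled

High-content screens for mitochondrial content stain confluent endothelial
monolayers with three dyes — a nuclear stain, an F-actin stain outlining each
cell, and a mitochondrion-accumulating dye — and image one site per well of a
384-well plate. The per-cell readouts are the total mitochondrial intensity
within the cytoplasm and the cytoplasm area; because mitochondrial content
and cell size are strongly coupled (approximately a power law, content
$\propto a\,A^{\gamma}$ with $\gamma \approx 1$ for cell area $A$), the
scientifically interesting compounds are the rare ones that move the
*size-normalized* intensity, i.e. dissociate content from size. mitoscreen
reimplements that whole computation — segmentation, measurement, plate
statistics and hit classification — and pairs it with a ground-truthed
synthetic image generator so that every stage can be tested quantitatively
without microscope data.

## The synthetic monolayer generator

`generate_scene()` builds one field as follows.

* **Geometry.** Cell centers are Poisson-disk sampled (dart throwing with a
  minimum spacing of $0.68\sqrt{HW/n}$ and a 6 px border margin, so every
  nucleus lies fully inside the field); the field is then tiled by the
  multiplicatively weighted Voronoi partition of the centers, with per-cell
  weights drawn around `cell_radius_mean_px` at CV `cell_radius_cv`. This
  produces touching, convex-ish cells of varying size — the flat confluent
  morphology that seeded-propagation segmentation is designed for. If the
  requested count cannot be placed, generation fails naming the achieved
  count rather than silently under-packing.
* **Effects.** A planted effect carries a content multiplier $c$, an area
  multiplier $f$ and a survival fraction $s$. In a confluent field an area
  multiplier cannot enlarge cells at fixed count, so $f$ is realised as
  $\mathrm{round}(n/f)$ cells tiling the same field; per-cell content is
  $a\,A^{\gamma}\,(c/f^{\gamma})$ times lognormal scatter (`content_cv`).
  Under this construction a *proportional* effect with fold $m$ (i.e.
  $f = m^{1/\gamma}$, $c = m$) scales mean area and mean total content by
  $m$ while leaving the content/area ratio untouched at $\gamma = 1$;
  a *mito-only* effect scales content alone; a *toxic* effect thins the
  tiling binomially, leaving background gaps where cells died.
* **Channels.** Nuclei render as bright disks (radius
  `nucleus_to_cell_radius_ratio` times the equivalent cell radius). The
  boundary channel has a moderate cytoplasm baseline and strong cortical
  ridges (40,000 AU) along every cell-cell interface — the contrast cue the
  propagation step keys on. Mitochondrial content is laid down as a clumped
  mixture-of-Gaussians density over the cytoplasm (clump scale 2.5 px, one
  clump per ~70 px²) plus a diffuse floor, normalised so the noiseless
  raster integrates exactly to the cell's content; a `nuclear_bleed_fraction`
  (default 8%) of the signal falls inside the nucleus footprint, which is
  why nucleus masking measurably improves the measurement.
* **Corruption.** `render_channels()` applies, in order, Gaussian optical
  blur (`blur_sigma_px`), a smooth multiplicative illumination field with
  max/min ratio exactly `1 + illumination_gradient_amplitude` (shared by all
  wells of a plate, per channel), Poisson shot noise with variance
  `poisson_scaling × intensity`, additive Gaussian read noise, and clipping
  to the 16-bit range. With all corruption parameters at zero the output
  equals the input raster, which the tests exploit.

Defaults were chosen once as plausible study conditions: a 256×256 px field
holding ~130 control cells (so the 40-cell toxicity cutoff sits at ~30% of
the control count), mean cell radius 12 px, weight CV 0.25, nucleus/cell
radius ratio 0.4, $\gamma = 1$, $a = 60$ AU/px (mitochondrial signal well
above the 20 AU read noise), content CV 0.25, per-well staining CV 0.03,
shot-noise gain 5, blur 1 px, shading amplitude 0.3. `simulate_cell_records()`
is the statistical fast path used for screen-scale simulations: it draws the
same per-cell quantities from the generative law directly (lognormal areas
with CV ≈ 2× the weight CV, calibrated once against rendered scenes) without
touching pixels; rendered and fast-path moments agree within ~10% and the
tests check that.

**What the generator does not emulate:** optical PSF structure beyond
Gaussian blur, z-dimension, photobleaching, spatial plate effects
(edge/gradient artifacts in well position), staining artifacts, debris, or
mitotic/apoptotic morphologies. Passing tests therefore certify the
*computational* contracts of the pipeline — segmentation against known
geometry, calibration of the statistics, recovery of planted effects — not
robustness to every failure mode of real screens (which the original assay
handled by manual review of hit images).

## The imaging chain

* **Illumination correction.** Per plate and channel, the mean of all well
  images is smoothed with a wide Gaussian (σ = width/10, replicate
  boundary), rescaled to unit mean and floored at $10^{-6}$; images are
  divided by the profile. The smoothing scale passes only slowly varying
  shading; the replicate boundary matters, since circular wrapping biases
  the profile near the edges. On flat-field frames (the standard calibration:
  a bright uniform target, frames averaged) correction reduces the CV of
  the averaged frame by ~8× and the estimated profile correlates with the
  planted field at r > 0.99.
* **Background thresholding.** The mitochondrial background cutoff comes
  from three-class Otsu: the pair $(t_{low}, t_{high})$ maximising the
  between-class variance over all histogram bin pairs (128 bins), computed
  by exhaustive vectorised search and cross-checked against a brute-force
  oracle. The middle class is assigned to *foreground* by default (cutoff =
  $t_{low}$): dim perinuclear mitochondrial signal sits between background
  and bright clumps, and discarding it would bias small-content cells
  downward. Background handling is *masking* (pixels below the cutoff
  contribute zero; pixels at or above it contribute their full intensity),
  with subtraction available as an option.
* **Nuclei.** Global two-class Otsu foreground, declumped by watershed on
  the Gaussian-smoothed distance transform, size-filtered to [10, 4000] px.
  The distance map is smoothed at σ = 1 px: at σ = 2 the peak-to-saddle gap
  of two nuclei 1.5 radii apart falls below the watershed tolerance (h = 1)
  and the pair merges, so the gentler smoothing is what keeps touching
  nuclei separable while still suppressing noise minima.
* **Cell boundaries.** Seeded propagation: multi-source Dijkstra over the
  pixel grid (8-connected) where one step from $p$ to $q$ costs
  $\sqrt{\lambda s^2 + (I(p)-I(q))^2}$, $s$ the spatial step length (1 or
  $\sqrt 2$). Implemented in C++ with a deterministic priority order — exact
  cost ties resolve to the smaller seed label, then the smaller pixel index.
  Intensities are normalised to unit range before costs, and the default
  regularization is λ = 0.001: with strongly contrast-marked boundaries a
  weak spatial term suffices, and larger λ drags boundaries toward the
  unweighted nearest-seed partition, degrading recovery of size-varying
  cells (measured: IoU ≥ 0.7 recall drops from ~0.98 at λ = 0.001 to ~0.86
  at λ = 0.05 under default conditions). Cells are propagated over the whole
  image, consistent with a confluent monolayer in which derived boundaries
  tile the field; in sparse (toxic) wells the gaps are therefore absorbed
  into the surviving cells and areas are overestimated — harmless downstream
  because such wells fall below the 40-cell toxicity filter, but a known
  limitation if the pipeline were pointed at sub-confluent cultures.
* **Measurement.** Cytoplasm is the cell footprint minus the nucleus (the
  partition invariants — nuclei within their cells, cytoplasm disjoint from
  nuclei, pixel counts conserved — are asserted on every run); per cell the
  pipeline reports nucleus/cell/cytoplasm areas in px², integrated
  mitochondrial intensity over the cytoplasm after background masking, and
  that total divided by cytoplasm area. Cells touching the image border are
  excluded by default (truncated cytoplasm biases both area and intensity).
  All coordinates are 0-based, intensities in arbitrary units; no physical
  calibration is used anywhere.

## Screen statistics

Per image, the median over included cells of each metric (cytoplasm area,
integrated intensity, size-normalized intensity) plus the cell count form
the well summary. Control wells are pooled per screening day and fitted
robustly (median, 1.4826·MAD; moment estimation available); a treated well's
score is $z = (x - \hat\mu_d)/\hat\sigma_d$ against its day's controls, and
replicates combine by Stouffer's method, $\sum z_i/\sqrt n$, which has unit
variance under the null and reduces to $z$ for a single replicate. Wells
with fewer than 40 cells are excluded before scoring (strictly: 39 fails,
40 passes), and a compound is a hit when its composite score on the
size-normalized metric strictly exceeds 1.98 (two-sided Gaussian tail
0.0477, under the conventional p < 0.05).

The default screen layout mirrors the assay design: every compound appears
once per screening day (biological duplicates across days) and each day
carries a full 384-well DMSO control plate. The size of the control pool is
not cosmetic: with only ~16 control wells per day the median/MAD scale
estimate has ~29% sampling CV, which inflates the across-compound variance
of composite z to ~1.5 and the null hit fraction to ~6%; with a control
plate per day the composite z over null compounds is calibrated (variance
1.00–1.05, null exceedance ~2.5–3% against the Gaussian 2.39% — the small
excess reflects the mild skew of medians of lognormally scattered cells).

**Effect classification.** On the composite scores of the three metrics:
`dissociated_up` if $z_{norm} > 1.98$, `dissociated_down` if
$z_{norm} < -1.98$, `proportional` if $|z_{norm}| \le 1$ while both
$z_{raw} > 1.98$ and $z_{area} > 1.98$, otherwise `none`. One property of
this rule deserves emphasis: a genuinely proportional compound leaves the
size-normalized metric at its null distribution, so its $z_{norm}$ is (by
the calibration just established) approximately standard normal, and no
band of ±1 can contain more than $P(|Z|\le 1) = 0.683$ of such compounds —
slightly less here, since proportionally enlarged cells are fewer per
confluent field and their medians noisier. The ±1 band is therefore a
*specific but deliberately insensitive* label: about a third of truly
proportional strong compounds are reported as `none` rather than
misclassified as dissociated, which is the right failure direction for a
hit-triage rule. Dissociation calling, by contrast, is highly sensitive: a
1.5× mito-only effect shifts $z_{norm}$ by an order of magnitude more than
its null scatter and is recovered essentially always.

## Secondary-assay calculators

qPCR quantities assume exponential amplification at fixed efficiency 2.0
(TaqMan assays without standard curves; the efficiency is exposed as a
parameter): mtDNA/nuDNA ratio $= 2^{Ct_{nu} - Ct_{mt}}$, and expression
folds by delta-delta-Ct against a reference transcript,
$2^{-\Delta\Delta Ct}$. Both are exact round-trips of planted values by
construction, and strictly monotone in each Ct in the expected direction.
Respiration folds are ratios of group means of OCR divided by the chosen
normalizer (cell count, cell volume, total protein, or none); the tests pin
the normalizer-dependence pattern (equal OCR with halved protein gives fold
2.0 under protein normalization and 1.0 under none). Group significance
testing is deliberately left to standard routines (`t.test`, `aov` with
multiplicity correction) rather than re-implemented.

## Numerical choices and degenerate inputs

* Otsu thresholds are upper bin edges; ties in the exhaustive search resolve
  to the first maximum in scan order, deterministically. Images with fewer
  than three distinct occupied bins are rejected as degenerate rather than
  thresholded arbitrarily.
* Propagation ties (exact equal path costs) resolve to the smaller seed
  label via the priority ordering, making labelings reproducible
  bit-for-bit; the test suite verifies pixel-for-pixel equality with an
  independent per-label Dijkstra oracle, including λ = 0 and the large-λ
  nearest-seed limit.
* Empty wells summarise to count 0 with missing medians; missing medians
  yield missing z; Stouffer combines only finite replicate scores and is NA
  on none. Zero control scale (constant control medians) is an error, not a
  silent division.
* Every well's RNG stream derives from `hash(master_seed, plate, well)`, so
  any subset of wells regenerates identically in any order, and whole runs
  are byte-reproducible (the run manifest records all parameters and the
  md5 of every output table).
* An empty-cytoplasm label makes the mitochondrial area fraction undefined
  and is reported as missing, never as 0.

## Problem sizes used by the test suite

The packaged tests run the oracle comparisons on 1,000 random 16-bin
histograms and 50 random 64×64 propagation instances at three λ values;
segmentation recovery on three rendered default scenes (~390 cells);
null calibration on twenty simulated duplicate screens of 368 compounds
each (pooled to estimate the mean, variance and tail fraction of composite
z precisely, with the tail compared against the binomial interval of one
368-compound screen); and planted-effect recovery on a screen of 40
mito-only and 40 proportional compounds plus 500 simulated toxic wells.
These sizes make the statistical assertions sharp while keeping the full
suite a few minutes of compute.

## Known limitations

Beyond the generator realism caveats above: the pipeline has no spatial
plate-effect correction (no B-score/median polish) because the generator
plants none; one imaging site per well is assumed throughout; the
propagation foreground is the whole field, appropriate only near
confluence; and hit confirmation by eye — which the original workflow used
to remove staining artifacts and segmentation errors — is out of scope, so
the hit list should be read as the automated stage of a triage funnel.
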