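# End-to-end orchestration: synthetic plates -> imaging -> screen statistics.

#' Assemble a screen run configuration
#'
#' Collects every parameter of a run in one validated list that is recorded
#' verbatim into the run manifest: the synthetic scene parameters, plate map
#' and planted effects, the imaging-chain settings and the screen-statistics
#' settings.
#'
#' @param platemap Plate-map data frame (see [generate_platemap()]).
#' @param effects Named list of [effect_spec]s for treatment compounds.
#' @param params [scene_params] for synthetic generation.
#' @param master_seed Integer master seed for the whole run.
#' @param measure `"truth"` (draw cell records from the generative model;
#'   fast, for screen-scale statistical simulations) or `"images"` (render,
#'   segment and measure every well's images).
#' @param out_dir Optional output directory for tables and the manifest.
#' @param lambda Propagation regularization.
#' @param otsu_bins Histogram bins of the three-class Otsu background cutoff.
#' @param middle_class_to Three-class middle-class assignment
#'   (`"foreground"` default).
#' @param min_nucleus_area_px,max_nucleus_area_px Nucleus size filter.
#' @param exclude_border Drop border-touching cells from measurement.
#' @param background Background handling of [measure_cells()].
#' @param estimator Control estimator (`"robust"`/`"moment"`).
#' @param min_cells Toxicity cutoff (default 40).
#' @param z_threshold Hit threshold (default 1.98).
#' @param z_null_band Null band of [classify_effect()].
#' @return A `screen_config` list.
#' @export
screen_config <- function(platemap, effects = list(), params = scene_params(),
                          master_seed = 1L,
                          measure = c("truth", "images"), out_dir = NULL,
                          lambda = 0.001, otsu_bins = 128L,
                          middle_class_to = "foreground",
                          min_nucleus_area_px = 10L,
                          max_nucleus_area_px = 4000L,
                          exclude_border = TRUE,
                          background = "mask",
                          estimator = "robust", min_cells = 40L,
                          z_threshold = 1.98, z_null_band = 1.0) {
  measure <- match.arg(measure)
  validate_platemap(platemap, effects)
  structure(list(platemap = platemap, effects = effects, params = params,
                 master_seed = as.integer(master_seed), measure = measure,
                 out_dir = out_dir,
                 imaging = list(lambda = lambda, otsu_bins = otsu_bins,
                                middle_class_to = middle_class_to,
                                min_nucleus_area_px = min_nucleus_area_px,
                                max_nucleus_area_px = max_nucleus_area_px,
                                exclude_border = exclude_border,
                                background = background),
                 stats = list(estimator = estimator, min_cells = min_cells,
                              z_threshold = z_threshold,
                              z_null_band = z_null_band)),
            class = "screen_config")
}

default_imaging <- function() {
  list(lambda = 0.001, otsu_bins = 128L, middle_class_to = "foreground",
       min_nucleus_area_px = 10L, max_nucleus_area_px = 4000L,
       exclude_border = TRUE, background = "mask")
}

# Internal: the partition contract of the segmentation masks.
check_partition <- function(cells, nuclei, cytoplasm) {
  nz <- nuclei > 0
  if (any(cells[nz] != nuclei[nz]))
    stop_ms("partition violation: nuclei not contained in matching cells")
  if (any(cytoplasm[nz] != 0))
    stop_ms("partition violation: cytoplasm overlaps nuclei")
  ids <- unique(cells[cells > 0])
  nb <- if (length(ids)) max(ids) else 0L
  if (nb > 0) {
    ok <- tabulate(cytoplasm, nb) + tabulate(nuclei, nb) == tabulate(cells, nb)
    if (!all(ok[ids]))
      stop_ms("partition violation: cytoplasm + nucleus != cell for label(s) %s",
              paste(head(ids[!ok[ids]], 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Segment and measure one well's corrected images
#'
#' The per-image analysis chain: nuclei from the nuclear stain, cell
#' boundaries by seeded propagation on the boundary stain, cytoplasm by
#' nucleus masking, background cutoff for the mitochondrial channel from
#' three-class Otsu, per-cell measurement. Mask partition invariants are
#' asserted on every call.
#'
#' @param imgs Named list of corrected [channel_image]s (`nuclear`,
#'   `boundary`, `mito`).
#' @param imaging List of imaging settings (see [screen_config()]).
#' @return List with `nuclei`, `cells`, `cytoplasm` label masks, the mito
#'   `background_cutoff`, and the `records` data frame.
#' @export
segment_well <- function(imgs, imaging = default_imaging()) {
  nuclei <- segment_nuclei(imgs$nuclear,
                           min_area_px = imaging$min_nucleus_area_px,
                           max_area_px = imaging$max_nucleus_area_px)
  cells <- propagate_cells(imgs$boundary, nuclei, lambda = imaging$lambda)
  cytoplasm <- cytoplasm_mask(cells, nuclei)
  check_partition(cells, nuclei, cytoplasm)
  cutoff <- tryCatch(
    otsu_three_class(imgs$mito$pixels, n_bins = imaging$otsu_bins,
                     middle_class_to = imaging$middle_class_to)$background_cutoff,
    error = function(e) 0)
  records <- measure_cells(cytoplasm, cells, nuclei, imgs$mito,
                           background_cutoff = cutoff,
                           exclude_border = imaging$exclude_border,
                           background = imaging$background)
  list(nuclei = nuclei, cells = cells, cytoplasm = cytoplasm,
       background_cutoff = cutoff, records = records)
}

#' Run a full synthetic screen
#'
#' Generates every well of the plate map under its planted effect, measures
#' per-cell records (either directly from the generative model or through
#' the full imaging chain), summarizes wells, fits day-matched control
#' distributions, scores compounds and calls hits. Deterministic given the
#' configuration and master seed. A well whose imaging fails is skipped with
#' a warning and listed in the manifest rather than aborting the run.
#'
#' @param config A [screen_config].
#' @return List with `well_summaries` (all wells, with `role` and
#'   `compound_id`), `scores`, `hits`, `truth_wells` (planted effects),
#'   `skipped_wells` and `manifest`. When `out_dir` is set, tables are
#'   written as CSV and the manifest as JSON, and the return value gains
#'   their md5 hashes.
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  pm <- config$platemap
  params <- config$params
  skipped <- character(0)
  summaries <- list()
  truth_wells <- list()

  process_records <- function(rw, records) {
    summarize_well(records, plate = rw$plate, well = rw$well, day = rw$day)
  }

  if (config$measure == "truth") {
    for (i in seq_len(nrow(pm))) {
      rw <- pm[i, ]
      eff <- if (rw$role == "control") effect_spec("null") else
        config$effects[[rw$compound_id]]
      recs <- simulate_cell_records(params, eff,
        rng_seed = derive_seed(config$master_seed, "scene", rw$plate, rw$well))
      summaries[[i]] <- process_records(rw, recs)
      truth_wells[[i]] <- data.frame(plate = rw$plate, well = rw$well,
                                     effect_class = eff$effect_class)
    }
  } else {
    for (pl in unique(pm$plate)) {
      sub <- pm[pm$plate == pl, , drop = FALSE]
      plate_out <- generate_plate(sub, config$effects, params,
                                  master_seed = config$master_seed)
      profiles <- lapply(setNames(nm = c("nuclear", "boundary", "mito")),
        function(ch) {
          imgs <- Filter(function(im) im$channel == ch, plate_out$images)
          estimate_illumination(imgs)
        })
      for (i in seq_len(nrow(sub))) {
        rw <- sub[i, ]
        res <- tryCatch({
          imgs <- lapply(setNames(nm = c("nuclear", "boundary", "mito")),
            function(ch) correct_illumination(
              plate_out$images[[paste(rw$plate, rw$well, 1, ch, sep = "_")]],
              profiles[[ch]]))
          segment_well(imgs, config$imaging)$records
        }, error = function(e) {
          warning(sprintf("well %s_%s skipped: %s", rw$plate, rw$well,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
        if (is.null(res)) {
          skipped <- c(skipped, paste(rw$plate, rw$well, sep = "_"))
        } else {
          summaries[[length(summaries) + 1L]] <- process_records(rw, res)
        }
      }
      tw <- plate_out$truth_wells
      truth_wells[[length(truth_wells) + 1L]] <-
        tw[, c("plate", "well", "effect_class")]
    }
  }
  well_summaries <- do.call(rbind, summaries)
  well_summaries <- merge(well_summaries,
                          pm[, c("plate", "well", "role", "compound_id")],
                          by = c("plate", "well"), sort = FALSE)
  ctrl <- well_summaries[well_summaries$role == "control", , drop = FALSE]
  trt <- well_summaries[well_summaries$role == "treatment", , drop = FALSE]
  scores <- if (nrow(trt) > 0)
    score_compounds(trt, ctrl, estimator = config$stats$estimator,
                    min_cells = config$stats$min_cells,
                    z_threshold = config$stats$z_threshold,
                    z_null_band = config$stats$z_null_band)
  else NULL
  hits <- if (!is.null(scores))
    call_hits(scores, "norm", config$stats$z_threshold) else NULL

  truth_wells <- unique(do.call(rbind, truth_wells))
  manifest <- list(
    master_seed = config$master_seed, measure = config$measure,
    params = unclass(params), imaging = config$imaging,
    stats = config$stats, n_wells = nrow(pm),
    skipped_wells = skipped, timestamp = NULL)

  out <- list(well_summaries = well_summaries, scores = scores, hits = hits,
              truth_wells = truth_wells, skipped_wells = skipped,
              manifest = manifest, config = config)
  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    if (!dir.exists(d)) dir.create(d, recursive = TRUE)
    write.csv(well_summaries, file.path(d, "wells.csv"), row.names = FALSE)
    if (!is.null(scores))
      write.csv(scores, file.path(d, "compounds.csv"), row.names = FALSE)
    if (!is.null(hits))
      write.csv(hits, file.path(d, "hits.csv"), row.names = FALSE)
    files <- list.files(d, pattern = "\\.csv$", full.names = TRUE)
    manifest$output_md5 <- as.list(tools::md5sum(files))
    names(manifest$output_md5) <- basename(files)
    jsonlite::write_json(manifest, file.path(d, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    out$manifest <- manifest
  }
  out
}

#' Summary figures for a completed screen run
#'
#' Renders the screen's headline views: the fold-change scatter of
#' mitochondrial intensity versus cytoplasm area per compound relative to
#' DMSO (null compounds cluster at (1,1), proportional compounds ride the
#' diagonal, size-dissociated compounds displace vertically), and the
#' frequency distributions of the composite Z-scores for the raw and
#' size-normalized metrics.
#'
#' @param result A [run_screen()] result (its `scores` must be present).
#' @param out_dir Directory the PNG figures are written into.
#' @return Invisibly, the list of ggplot objects (`scatter`, `hist_raw`,
#'   `hist_norm`).
#' @export
report_screen <- function(result, out_dir) {
  scores <- result$scores
  if (is.null(scores) || nrow(scores) == 0) stop_ms("result has no compound scores")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sc <- scores[complete.cases(scores[, c("fold_change_mito", "fold_change_area")]), ]
  p_scatter <- ggplot2::ggplot(sc,
      ggplot2::aes(x = fold_change_area, y = fold_change_mito,
                   colour = effect_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "cytoplasm area, fold vs DMSO",
                  y = "MitoTracker-like intensity, fold vs DMSO",
                  colour = "effect class") +
    ggplot2::theme_minimal()
  hist_of <- function(values, lab) {
    df <- data.frame(z = values[is.finite(values)])
    ggplot2::ggplot(df, ggplot2::aes(x = z)) +
      ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "white") +
      ggplot2::geom_vline(xintercept = 1.98, linetype = 2, colour = "red") +
      ggplot2::labs(x = lab, y = "compounds") +
      ggplot2::theme_minimal()
  }
  p_raw <- hist_of(scores$composite_z_raw,
                   "composite Z, integrated mito intensity")
  p_norm <- hist_of(scores$composite_z_norm,
                    "composite Z, size-normalized intensity")
  ggplot2::ggsave(file.path(out_dir, "fold_scatter.png"), p_scatter,
                  width = 6, height = 5, dpi = 150)
  ggplot2::ggsave(file.path(out_dir, "z_raw_hist.png"), p_raw,
                  width = 6, height = 4, dpi = 150)
  ggplot2::ggsave(file.path(out_dir, "z_norm_hist.png"), p_norm,
                  width = 6, height = 4, dpi = 150)
  invisible(list(scatter = p_scatter, hist_raw = p_raw, hist_norm = p_norm))
}
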