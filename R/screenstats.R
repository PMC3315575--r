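# Plate-level statistics: per-well medians, day-matched control
# distributions, robust Z-scores, Stouffer composites, toxicity filtering,
# hit calling and effect classification.

METRICS <- c(area = "median_cyto_area_px",
             raw = "median_integrated_mito_au",
             norm = "median_normalized_mito_au_per_px")

#' Summarize one well's cell records
#'
#' Medians of cytoplasm area, integrated mitochondrial intensity and
#' area-normalized intensity over the included (non-border) cells of one
#' image, plus the cell count. An empty record set yields count 0 and
#' missing medians.
#'
#' @param records Data frame of cell records (see [measure_cells()]).
#' @param plate,well,day Optional identity carried into the summary.
#' @return One-row data frame (`WellSummary`).
#' @export
summarize_well <- function(records, plate = NA_character_,
                           well = NA_character_, day = NA_integer_) {
  data.frame(
    plate = plate, well = well, day = day,
    cell_count = nrow(records),
    median_cyto_area_px = median_or_na(records$cytoplasm_area_px),
    median_integrated_mito_au = median_or_na(records$integrated_mito_intensity_au),
    median_normalized_mito_au_per_px =
      median_or_na(records$normalized_mito_intensity_au_per_px))
}

#' Summarize every well of a per-cell table
#'
#' @param cell_table Data frame of cell records with `plate`, `well`, `day`
#'   columns.
#' @return Data frame of well summaries, one row per (plate, well).
#' @export
summarize_wells <- function(cell_table) {
  stopifnot(all(c("plate", "well", "day") %in% names(cell_table)))
  keys <- unique(cell_table[, c("plate", "well", "day")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- cell_table$plate == keys$plate[i] & cell_table$well == keys$well[i]
    summarize_well(cell_table[sel, , drop = FALSE],
                   plate = keys$plate[i], well = keys$well[i],
                   day = keys$day[i])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit per-day control distributions
#'
#' Location and scale of the DMSO control wells' summary metrics, per
#' screening day and metric. The robust default uses the median and
#' `1.4826 * MAD`; the `moment` estimator uses mean and standard deviation.
#'
#' @param summaries Control well summaries (see [summarize_well()]) with a
#'   `day` column.
#' @param estimator `"robust"` (default) or `"moment"`.
#' @param min_controls Minimum control wells per day (default 3).
#' @return Data frame with `day`, `metric`, `location`, `scale`, `n`,
#'   `estimator`.
#' @export
fit_controls <- function(summaries, estimator = c("robust", "moment"),
                         min_controls = 3L) {
  estimator <- match.arg(estimator)
  rows <- list()
  for (d in sort(unique(summaries$day))) {
    sub <- summaries[summaries$day == d, , drop = FALSE]
    if (nrow(sub) < min_controls)
      stop_ms("day %s has only %d control wells (need >= %d)",
              d, nrow(sub), min_controls)
    for (m in names(METRICS)) {
      v <- sub[[METRICS[[m]]]]
      v <- v[is.finite(v)]
      if (length(v) < min_controls)
        stop_ms("day %s has only %d finite control values for metric %s",
                d, length(v), m)
      loc <- if (estimator == "robust") median(v) else mean(v)
      sc <- if (estimator == "robust") mad(v) else sd(v)
      if (!is.finite(sc) || sc <= 0)
        stop_ms("degenerate controls on day %s, metric %s: zero scale", d, m)
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, metric = m, location = loc, scale = sc,
        n = length(v), estimator = estimator)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Z-scores of well summaries against day-matched controls
#'
#' `z = (value - location) / scale` per metric, using the control
#' distribution of the well's screening day. Missing medians (empty wells)
#' yield missing z.
#'
#' @param summaries Well summaries with a `day` column.
#' @param controls Control fit from [fit_controls()].
#' @return `summaries` with added columns `z_area`, `z_raw`, `z_norm`.
#' @export
well_z <- function(summaries, controls) {
  out <- summaries
  for (m in names(METRICS)) {
    zc <- rep(NA_real_, nrow(out))
    for (d in unique(out$day)) {
      cf <- controls[controls$day == d & controls$metric == m, , drop = FALSE]
      if (nrow(cf) != 1L)
        stop_ms("no control distribution for day %s, metric %s", d, m)
      sel <- out$day == d
      zc[sel] <- (out[[METRICS[[m]]]][sel] - cf$location) / cf$scale
    }
    out[[paste0("z_", m)]] <- zc
  }
  out
}

#' Stouffer composite of replicate Z-scores
#'
#' `sum(z) / sqrt(n)` over the finite replicate scores: unit variance under
#' the null for independent replicates, and equal to `z` for a single
#' replicate. An empty input yields `NA`.
#'
#' @param z Numeric vector of replicate z-scores.
#' @return The composite Z (scalar).
#' @export
composite_z <- function(z) {
  z <- z[is.finite(z)]
  if (length(z) == 0L) return(NA_real_)
  sum(z) / sqrt(length(z))
}

#' Toxicity filter on well cell counts
#'
#' A well passes if at least `min_cells` cells were measured in its image
#' (strict reading: 39 cells fail, 40 pass). The default of 40 corresponds
#' to about 30% of the average negative-control cell count.
#'
#' @param cell_count Integer vector of well cell counts (or a well summary
#'   data frame with a `cell_count` column).
#' @param min_cells Minimum cell count (default 40).
#' @return Logical vector: `TRUE` = retained.
#' @export
toxicity_filter <- function(cell_count, min_cells = 40L) {
  if (is.data.frame(cell_count)) cell_count <- cell_count$cell_count
  cell_count >= min_cells
}

#' Per-compound fold changes relative to day-matched controls
#'
#' For each replicate well, the well median divided by the mean of the
#' same-day control medians; replicate folds are then averaged per compound.
#' Computed for integrated mitochondrial intensity and cytoplasm area.
#'
#' @param summaries Treatment well summaries with `compound_id` and `day`.
#' @param control_summaries Control well summaries with `day`.
#' @return Data frame `compound_id`, `fold_change_mito`, `fold_change_area`,
#'   `n_replicates`.
#' @export
fold_changes <- function(summaries, control_summaries) {
  ctrl_mean <- function(d, col) {
    v <- control_summaries[[col]][control_summaries$day == d]
    v <- v[is.finite(v)]
    if (length(v) == 0L) stop_ms("no control medians for day %s", d)
    mv <- mean(v)
    if (mv == 0) stop_ms("zero control mean for day %s", d)
    mv
  }
  s <- summaries
  s$f_mito <- NA_real_; s$f_area <- NA_real_
  for (d in unique(s$day)) {
    sel <- s$day == d
    s$f_mito[sel] <- s$median_integrated_mito_au[sel] /
      ctrl_mean(d, "median_integrated_mito_au")
    s$f_area[sel] <- s$median_cyto_area_px[sel] /
      ctrl_mean(d, "median_cyto_area_px")
  }
  cmp <- unique(s$compound_id)
  out <- data.frame(
    compound_id = cmp,
    fold_change_mito = vapply(cmp, function(cc)
      mean(s$f_mito[s$compound_id == cc], na.rm = TRUE), numeric(1)),
    fold_change_area = vapply(cmp, function(cc)
      mean(s$f_area[s$compound_id == cc], na.rm = TRUE), numeric(1)),
    n_replicates = vapply(cmp, function(cc)
      sum(s$compound_id == cc), integer(1)))
  rownames(out) <- NULL
  out
}

#' Classify a compound's effect as proportional or size-dissociated
#'
#' Operational rule on the composite Z-scores of the three metrics:
#' `dissociated_up` if the size-normalized score exceeds the hit threshold,
#' `dissociated_down` if it falls below its negative; `proportional` if the
#' normalized score sits inside the null band while both the raw
#' mitochondrial and the area scores exceed the hit threshold (content and
#' size moved together); otherwise `none`.
#'
#' @param z_raw,z_area,z_norm Composite Z vectors for the integrated-mito,
#'   cytoplasm-area and normalized metrics.
#' @param z_hit Hit threshold (default 1.98).
#' @param z_null_band Null band for the normalized score (default 1.0).
#' @return Character vector of effect classes.
#' @export
classify_effect <- function(z_raw, z_area, z_norm, z_hit = 1.98,
                            z_null_band = 1.0) {
  cls <- rep(NA_character_, length(z_norm))
  ok <- is.finite(z_norm)
  cls[ok & z_norm > z_hit] <- "dissociated_up"
  cls[ok & z_norm < -z_hit] <- "dissociated_down"
  prop <- ok & abs(z_norm) <= z_null_band &
    is.finite(z_raw) & z_raw > z_hit & is.finite(z_area) & z_area > z_hit
  cls[prop] <- "proportional"
  cls[ok & is.na(cls)] <- "none"
  cls
}

#' Score all compounds of a screen
#'
#' Combines replicate wells per compound: toxicity filtering, per-replicate
#' Z-scores against day-matched controls, Stouffer composite Z per metric,
#' fold changes relative to controls, hit status on the size-normalized
#' metric, and the effect class. Composite scores and folds use only
#' replicates passing the toxicity filter.
#'
#' @param well_summaries Treatment well summaries with `compound_id`, `day`.
#' @param control_summaries Control well summaries with `day`.
#' @param estimator Control estimator, `"robust"` (default) or `"moment"`.
#' @param min_cells Toxicity cutoff (default 40).
#' @param z_threshold Hit threshold on composite Z (default 1.98, p < 0.05).
#' @param z_null_band Null band of [classify_effect()].
#' @return Data frame of compound scores (`CompoundScore`): composite Z per
#'   metric, replicate counts, `passed_toxicity`, `is_hit`, `effect_class`,
#'   fold changes.
#' @export
score_compounds <- function(well_summaries, control_summaries,
                            estimator = "robust", min_cells = 40L,
                            z_threshold = 1.98, z_null_band = 1.0) {
  controls <- fit_controls(control_summaries, estimator = estimator)
  zs <- well_z(well_summaries, controls)
  zs$pass <- toxicity_filter(zs$cell_count, min_cells)
  cmp <- unique(zs$compound_id)
  rows <- lapply(cmp, function(cc) {
    sub <- zs[zs$compound_id == cc, , drop = FALSE]
    ok <- sub[sub$pass, , drop = FALSE]
    data.frame(
      compound_id = cc,
      n_replicates = nrow(sub),
      n_passing = nrow(ok),
      passed_toxicity = nrow(ok) > 0,
      composite_z_raw = composite_z(ok$z_raw),
      composite_z_area = composite_z(ok$z_area),
      composite_z_norm = composite_z(ok$z_norm))
  })
  out <- do.call(rbind, rows)
  passing <- zs[zs$pass, , drop = FALSE]
  if (nrow(passing) > 0) {
    fc <- fold_changes(passing, control_summaries)
    out <- merge(out, fc[, c("compound_id", "fold_change_mito",
                             "fold_change_area")],
                 by = "compound_id", all.x = TRUE, sort = FALSE)
  } else {
    out$fold_change_mito <- NA_real_
    out$fold_change_area <- NA_real_
  }
  out$is_hit <- out$passed_toxicity & is.finite(out$composite_z_norm) &
    out$composite_z_norm > z_threshold
  out$effect_class <- classify_effect(out$composite_z_raw,
                                      out$composite_z_area,
                                      out$composite_z_norm,
                                      z_hit = z_threshold,
                                      z_null_band = z_null_band)
  rownames(out) <- NULL
  out
}

#' Call hits from compound scores
#'
#' A compound is a hit when it passed the toxicity filter and its composite
#' Z for the chosen metric strictly exceeds the threshold.
#'
#' @param scores Compound scores from [score_compounds()].
#' @param metric `"norm"` (default), `"raw"` or `"area"`.
#' @param z_threshold Strict threshold (default 1.98).
#' @return The hit rows of `scores`, ordered by decreasing composite Z.
#' @export
call_hits <- function(scores, metric = c("norm", "raw", "area"),
                      z_threshold = 1.98) {
  metric <- match.arg(metric)
  col <- paste0("composite_z_", metric)
  sel <- scores$passed_toxicity & is.finite(scores[[col]]) &
    scores[[col]] > z_threshold
  hits <- scores[sel, , drop = FALSE]
  hits[order(-hits[[col]]), , drop = FALSE]
}
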