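# Plate-scale synthetic generation: plate maps, per-well seeding, rendering.

well_ids_384 <- function(n = 384L) {
  rows <- LETTERS[1:16]
  ids <- as.vector(t(outer(rows, sprintf("%02d", 1:24), paste0)))
  ids[seq_len(n)]
}

#' Build a screen plate map
#'
#' Lays out a duplicate screen the way the source assay was run: each
#' compound appears once per screening day (biological duplicates across
#' days), and every day additionally carries one full 384-well DMSO negative
#' control plate.
#'
#' @param compound_ids Character vector of compound identifiers.
#' @param n_days Number of screening days / replicates (default 2).
#' @param wells_per_plate Number of wells per plate (default 384).
#' @param dose_uM Dose annotation for treatment wells.
#' @param control_plate If `TRUE` (default), add one all-DMSO control plate
#'   per day; if `FALSE`, reserve `inplate_controls` wells on each compound
#'   plate for DMSO instead.
#' @param inplate_controls Number of in-plate DMSO wells when
#'   `control_plate = FALSE`.
#' @return Data frame with columns `plate`, `well`, `day`, `role`
#'   (`control`/`treatment`), `compound_id`, `dose_uM`.
#' @export
generate_platemap <- function(compound_ids, n_days = 2L, wells_per_plate = 384L,
                              dose_uM = 10, control_plate = TRUE,
                              inplate_controls = 16L) {
  stopifnot(length(compound_ids) >= 1L, !anyDuplicated(compound_ids))
  per_plate <- if (control_plate) wells_per_plate else wells_per_plate - inplate_controls
  n_plates <- ceiling(length(compound_ids) / per_plate)
  rows <- list()
  for (d in seq_len(n_days)) {
    if (control_plate) {
      rows[[length(rows) + 1L]] <- data.frame(
        plate = sprintf("D%dC", d), well = well_ids_384(wells_per_plate),
        day = d, role = "control", compound_id = "DMSO", dose_uM = 0)
    }
    for (p in seq_len(n_plates)) {
      idx <- ((p - 1L) * per_plate + 1L):min(p * per_plate, length(compound_ids))
      cmp <- compound_ids[idx]
      wells <- well_ids_384(wells_per_plate)
      if (control_plate) {
        tw <- wells[seq_along(cmp)]
        rows[[length(rows) + 1L]] <- data.frame(
          plate = sprintf("D%dT%d", d, p), well = tw, day = d,
          role = "treatment", compound_id = cmp, dose_uM = dose_uM)
      } else {
        ctrl_w <- wells[seq_len(inplate_controls)]
        trt_w <- wells[inplate_controls + seq_along(cmp)]
        rows[[length(rows) + 1L]] <- data.frame(
          plate = sprintf("D%dT%d", d, p),
          well = c(ctrl_w, trt_w), day = d,
          role = c(rep("control", inplate_controls), rep("treatment", length(cmp))),
          compound_id = c(rep("DMSO", inplate_controls), cmp),
          dose_uM = c(rep(0, inplate_controls), rep(dose_uM, length(cmp))))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

validate_platemap <- function(platemap, effects = NULL) {
  need <- c("plate", "well", "day", "role", "compound_id")
  miss <- setdiff(need, names(platemap))
  if (length(miss) > 0)
    stop_ms("plate map is missing columns: %s", paste(miss, collapse = ", "))
  key <- paste(platemap$plate, platemap$well)
  if (anyDuplicated(key))
    stop_ms("plate map has duplicated (plate, well) entries: %s",
            paste(head(unique(key[duplicated(key)]), 3), collapse = ", "))
  if (!all(platemap$role %in% c("control", "treatment")))
    stop_ms("plate map roles must be 'control' or 'treatment'")
  for (d in unique(platemap$day)) {
    if (!any(platemap$role[platemap$day == d] == "control"))
      stop_ms("screening day %s has no control wells", d)
  }
  if (!is.null(effects)) {
    trt <- unique(platemap$compound_id[platemap$role == "treatment"])
    miss <- setdiff(trt, names(effects))
    if (length(miss) > 0)
      stop_ms("no effect specification for compound(s): %s",
              paste(head(miss, 5), collapse = ", "))
  }
  invisible(platemap)
}

#' Generate a full synthetic plate of channel images with ground truth
#'
#' Renders one image site per well for every well of the plate map. Each
#' well's scene is seeded deterministically from `master_seed`, the plate and
#' the well id, so any subset of wells can be regenerated independently and
#' identically. All wells of one plate share a plate-specific illumination
#' field per channel (what the retrospective illumination correction
#' estimates).
#'
#' @param platemap Plate-map data frame (see [generate_platemap()]).
#' @param effects Named list mapping `compound_id` to [effect_spec]s;
#'   control wells use the null effect.
#' @param params A [scene_params].
#' @param master_seed Integer master seed.
#' @param out_dir Optional directory: if given, images are written as 16-bit
#'   TIFFs named `{plate}_{well}_{site}_{channel}.tif` and the ground-truth
#'   tables as CSV files alongside.
#' @param keep_images Keep rendered images in the returned list (default
#'   TRUE; set FALSE for large plates written to disk).
#' @return List with `images` (named list of [channel_image]s),
#'   `truth_cells`, `truth_wells`, `platemap` and the per-plate illumination
#'   `fields`.
#' @export
generate_plate <- function(platemap, effects = list(), params = scene_params(),
                           master_seed = 1L, out_dir = NULL,
                           keep_images = TRUE) {
  validate_platemap(platemap, effects)
  H <- params$image_height_px; W <- params$image_width_px
  fields <- list()
  for (pl in unique(platemap$plate)) {
    set.seed(derive_seed(master_seed, "illum", pl))
    ctr <- runif(2, 0.25, 0.75)
    fields[[pl]] <- lapply(setNames(nm = c("nuclear", "boundary", "mito")),
      function(ch) illumination_field(H, W, params$illumination_gradient_amplitude,
                                      center_frac = ctr))
  }
  images <- list()
  cells <- list()
  wellrows <- list()
  for (i in seq_len(nrow(platemap))) {
    rw <- platemap[i, ]
    eff <- if (rw$role == "control") effect_spec("null") else effects[[rw$compound_id]]
    sd_scene <- derive_seed(master_seed, "scene", rw$plate, rw$well)
    sd_noise <- derive_seed(master_seed, "noise", rw$plate, rw$well)
    scene <- generate_scene(params, eff, rng_seed = sd_scene)
    imgs <- render_channels(scene$rasters, params, rng_seed = sd_noise,
                            illumination = fields[[rw$plate]],
                            plate = rw$plate, well = rw$well, site = 1L,
                            day = rw$day)
    if (!is.null(out_dir)) {
      for (img in imgs) write_channel_image(img, out_dir, params$bit_depth)
    }
    if (keep_images) {
      for (img in imgs) images[[image_key(img)]] <- img
    }
    tr <- scene$truth
    if (nrow(tr) > 0) {
      tr$plate <- rw$plate; tr$well <- rw$well; tr$day <- rw$day
      cells[[length(cells) + 1L]] <- tr
    }
    wellrows[[length(wellrows) + 1L]] <- data.frame(
      plate = rw$plate, well = rw$well, day = rw$day, role = rw$role,
      compound_id = rw$compound_id,
      effect_class = eff$effect_class,
      content_multiplier = eff$content_multiplier,
      area_multiplier = eff$area_multiplier,
      survival_fraction = eff$survival_fraction,
      n_cells_true = nrow(tr), well_effect = scene$well_effect)
  }
  truth_cells <- if (length(cells) > 0) do.call(rbind, cells) else
    data.frame()
  truth_wells <- do.call(rbind, wellrows)
  rownames(truth_cells) <- rownames(truth_wells) <- NULL
  if (!is.null(out_dir)) {
    write.csv(truth_cells, file.path(out_dir, "truth_cells.csv"), row.names = FALSE)
    write.csv(truth_wells, file.path(out_dir, "truth_wells.csv"), row.names = FALSE)
    write.csv(platemap, file.path(out_dir, "platemap.csv"), row.names = FALSE)
  }
  list(images = images, truth_cells = truth_cells, truth_wells = truth_wells,
       platemap = platemap, fields = fields)
}
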