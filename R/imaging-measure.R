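# Per-cell measurement and mask arithmetic.

#' Measure per-cell mitochondrial content and morphology
#'
#' For every cell label: nucleus, cell and cytoplasm pixel areas, the total
#' mitochondrial intensity over the cell's cytoplasm after background
#' handling, and that total normalized to cytoplasm area. Background
#' handling is `"mask"` by default (pixels below the cutoff contribute 0,
#' pixels at/above it contribute their full intensity — a background
#' threshold, not a subtraction); `"subtract"` subtracts the cutoff and
#' clamps at zero. Cells touching the image border are flagged and, by
#' default, excluded (truncated cytoplasm biases both area and intensity).
#'
#' @param cytoplasm,cells,nuclei Integer label masks sharing one label set
#'   (see [cytoplasm_mask()]).
#' @param mito [channel_image] (or matrix) of the corrected mitochondrial
#'   channel.
#' @param background_cutoff Background cutoff in AU (e.g. the `t_low` of
#'   [otsu_three_class()] with the middle class as foreground).
#' @param exclude_border Drop border-touching cells (default TRUE).
#' @param background `"mask"` (default) or `"subtract"`.
#' @return Data frame of cell records: `cell_id`, `nucleus_area_px`,
#'   `cell_area_px`, `cytoplasm_area_px`, `integrated_mito_intensity_au`,
#'   `normalized_mito_intensity_au_per_px`, `touches_border`.
#' @export
measure_cells <- function(cytoplasm, cells, nuclei, mito,
                          background_cutoff = 0, exclude_border = TRUE,
                          background = c("mask", "subtract")) {
  background <- match.arg(background)
  I <- if (inherits(mito, "channel_image")) mito$pixels else as.matrix(mito)
  cytoplasm <- as.matrix(cytoplasm); cells <- as.matrix(cells)
  nuclei <- as.matrix(nuclei)
  if (!all(dim(I) == dim(cytoplasm)) || !all(dim(cells) == dim(cytoplasm)) ||
      !all(dim(nuclei) == dim(cytoplasm)))
    stop_ms("masks and mito image must have identical dimensions")
  ids <- sort(unique(cells[cells > 0]))
  if (length(ids) == 0L)
    return(data.frame(cell_id = integer(), nucleus_area_px = integer(),
                      cell_area_px = integer(), cytoplasm_area_px = integer(),
                      integrated_mito_intensity_au = numeric(),
                      normalized_mito_intensity_au_per_px = numeric(),
                      touches_border = logical()))
  nb <- max(ids)
  cell_area <- tabulate(cells, nbins = nb)
  nuc_area <- tabulate(nuclei, nbins = nb)
  cyto_area <- tabulate(cytoplasm, nbins = nb)
  contrib <- if (background == "mask") I * (I >= background_cutoff)
             else pmax(I - background_cutoff, 0)
  sel <- cytoplasm > 0
  integrated <- rep(0, nb)
  if (any(sel)) {
    s <- rowsum(contrib[sel], group = cytoplasm[sel])
    integrated[as.integer(rownames(s))] <- s[, 1]
  }
  H <- nrow(cells); W <- ncol(cells)
  border_ids <- unique(c(cells[1, ], cells[H, ], cells[, 1], cells[, W]))
  rec <- data.frame(
    cell_id = ids,
    nucleus_area_px = nuc_area[ids],
    cell_area_px = cell_area[ids],
    cytoplasm_area_px = cyto_area[ids],
    integrated_mito_intensity_au = integrated[ids],
    normalized_mito_intensity_au_per_px =
      ifelse(cyto_area[ids] > 0, integrated[ids] / cyto_area[ids], NA_real_),
    touches_border = ids %in% border_ids)
  if (exclude_border) rec <- rec[!rec$touches_border, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Fraction of cytoplasmic area occupied by mitochondrial signal
#'
#' Mask arithmetic version of the "% cytoplasmic area occupied by
#' mitochondria" readout: per cytoplasm label, the fraction of its pixels
#' inside the mitochondrial foreground mask, plus the overall fraction over
#' all cytoplasm pixels. A label with empty cytoplasm is reported as `NA`
#' (undefined), not 0.
#'
#' @param mito_foreground Logical (or 0/1) matrix of mitochondrial
#'   foreground.
#' @param cytoplasm Integer cytoplasm label mask of the same shape.
#' @return List with `per_label` (data frame `label`, `fraction`) and
#'   `overall`.
#' @export
mito_area_fraction <- function(mito_foreground, cytoplasm) {
  fg <- as.matrix(mito_foreground) > 0
  cytoplasm <- as.matrix(cytoplasm)
  if (!all(dim(fg) == dim(cytoplasm)))
    stop_ms("masks must have identical dimensions")
  ids <- sort(unique(cytoplasm[cytoplasm > 0]))
  nb <- if (length(ids) > 0) max(ids) else 0L
  denom <- tabulate(cytoplasm, nbins = nb)
  numer <- tabulate(cytoplasm[fg], nbins = nb)
  per <- data.frame(label = ids,
                    fraction = ifelse(denom[ids] > 0,
                                      numer[ids] / denom[ids], NA_real_))
  overall <- if (sum(denom) > 0) sum(numer) / sum(denom) else NA_real_
  list(per_label = per, overall = overall)
}

#' Match predicted cells to ground-truth cells by IoU
#'
#' Greedy one-to-one matching of predicted to true labels in decreasing
#' intersection-over-union order, used to score segmentation recovery.
#'
#' @param truth,pred Integer label masks of identical shape.
#' @param iou_min Minimum IoU for a pair to count as matched.
#' @return List with `matches` (data frame `truth`, `pred`, `iou`) and
#'   `recall` (fraction of truth labels with a match at `iou_min`).
#' @export
match_segmentation <- function(truth, pred, iou_min = 0.7) {
  truth <- as.matrix(truth); pred <- as.matrix(pred)
  stopifnot(all(dim(truth) == dim(pred)))
  t_ids <- sort(unique(truth[truth > 0]))
  if (length(t_ids) == 0L)
    return(list(matches = data.frame(truth = integer(), pred = integer(),
                                     iou = numeric()), recall = NA_real_))
  sel <- truth > 0 & pred > 0
  if (!any(sel))
    return(list(matches = data.frame(truth = integer(), pred = integer(),
                                     iou = numeric()), recall = 0))
  ov <- as.data.frame(table(truth = truth[sel], pred = pred[sel]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0, ]
  ov$truth <- as.integer(ov$truth); ov$pred <- as.integer(ov$pred)
  t_area <- tabulate(truth, nbins = max(truth))
  p_area <- tabulate(pred, nbins = max(pred))
  ov$iou <- ov$Freq / (t_area[ov$truth] + p_area[ov$pred] - ov$Freq)
  ov <- ov[order(-ov$iou), ]
  used_t <- integer(0); used_p <- integer(0)
  keep <- logical(nrow(ov))
  for (r in seq_len(nrow(ov))) {
    if (!(ov$truth[r] %in% used_t) && !(ov$pred[r] %in% used_p)) {
      keep[r] <- TRUE
      used_t <- c(used_t, ov$truth[r]); used_p <- c(used_p, ov$pred[r])
    }
  }
  m <- ov[keep & ov$iou >= iou_min, c("truth", "pred", "iou")]
  rownames(m) <- NULL
  list(matches = m, recall = nrow(m) / length(t_ids))
}
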