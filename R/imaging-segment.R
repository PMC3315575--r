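# Nuclei identification and propagation-based cell boundary segmentation.

#' Segment nuclei from the nuclear-stain channel
#'
#' Global two-class Otsu foreground, declumped by watershed on the
#' Gaussian-smoothed distance transform (minima suppression via the
#' watershed tolerance), then size-filtered. Returns one integer label per
#' nucleus; labels need not be contiguous after size filtering. A blank
#' image yields an empty mask.
#'
#' @param img A [channel_image] (`nuclear`), illumination-corrected.
#' @param min_area_px,max_area_px Nucleus size filter in pixels.
#' @param smooth_sigma_px Gaussian sigma applied to the distance transform
#'   before watershed (default 1; heavier smoothing flattens the saddle
#'   between close nuclei and defeats declumping).
#' @param h Watershed minima-suppression tolerance (default 1).
#' @param threshold Optional fixed foreground cutoff in AU; defaults to the
#'   global two-class Otsu threshold.
#' @return Integer label matrix (0 = background).
#' @export
segment_nuclei <- function(img, min_area_px = 10L, max_area_px = 4000L,
                           smooth_sigma_px = 1, h = 1, threshold = NULL) {
  stopifnot(inherits(img, "channel_image"))
  x <- img$pixels
  if (diff(range(x)) == 0) return(matrix(0L, nrow(x), ncol(x)))
  thr <- threshold %||% otsu_two_class(x)
  bw <- x > thr
  if (!any(bw)) return(matrix(0L, nrow(x), ncol(x)))
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  dm_s <- EBImage::gblur(dm, sigma = smooth_sigma_px)
  dm_s[!bw] <- 0
  ws <- EBImage::watershed(EBImage::Image(dm_s), tolerance = h, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(x), ncol(x))
  lab[!bw] <- 0L
  sizes <- tabulate(lab)
  drop <- which(sizes < min_area_px | sizes > max_area_px)
  if (length(drop) > 0) lab[lab %in% drop] <- 0L
  lab
}

#' Seeded propagation of cell boundaries from nuclei
#'
#' Assigns every reachable foreground pixel to the nucleus seed with minimal
#' accumulated path cost, where one step from pixel `p` to neighbour `q`
#' costs `sqrt(lambda * s^2 + (I(p) - I(q))^2)` (`s` = spatial step length, 1
#' or `sqrt(2)`). Small `lambda` makes boundaries follow intensity structure
#' (the bright F-actin ridges between cells); large `lambda` converges to the
#' nearest-seed spatial partition. Equal path costs resolve to the smaller
#' seed label. Seed pixels keep their own labels; unreachable foreground
#' stays 0.
#'
#' @param boundary A [channel_image] of the cell-boundary stain
#'   (illumination-corrected), or a plain numeric matrix.
#' @param nuclei Integer label matrix of seeds (from [segment_nuclei()]).
#' @param foreground Optional logical matrix restricting propagation; default
#'   the whole image (a confluent monolayer leaves negligible background).
#' @param lambda Nonnegative spatial regularization weight.
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @param normalize Divide intensities by the bit-depth maximum before
#'   computing step costs (default TRUE), so `lambda` keeps its conventional
#'   scale for unit-range images.
#' @param bit_depth Bit depth used by `normalize`.
#' @return Integer label matrix of cells (labels match the nucleus seeds).
#' @export
propagate_cells <- function(boundary, nuclei, foreground = NULL,
                            lambda = 0.001, connectivity = 8L,
                            normalize = TRUE, bit_depth = 16L) {
  x <- if (inherits(boundary, "channel_image")) boundary$pixels else as.matrix(boundary)
  storage.mode(x) <- "double"
  if (lambda < 0) stop_ms("lambda must be >= 0")
  if (!connectivity %in% c(4L, 8L)) stop_ms("connectivity must be 4 or 8")
  nuclei <- as.matrix(nuclei); storage.mode(nuclei) <- "integer"
  if (is.null(foreground)) foreground <- matrix(TRUE, nrow(x), ncol(x))
  if (!all(dim(x) == dim(nuclei)) || !all(dim(x) == dim(foreground)))
    stop_ms("boundary, nuclei and foreground must have identical dimensions")
  if (any(nuclei > 0 & !foreground))
    stop_ms("nuclei seeds must lie inside the foreground")
  if (!any(nuclei > 0)) {
    if (any(foreground)) warning("no seeds: returning an all-zero label mask")
    return(matrix(0L, nrow(x), ncol(x)))
  }
  if (normalize) x <- x / (2^bit_depth - 1)
  cpp_propagate(x, nuclei, foreground, lambda, as.integer(connectivity))
}

#' Define cytoplasm by masking nuclei out of cells
#'
#' The cytoplasm of cell `k` is its cell footprint minus all nucleus pixels.
#' Each nucleus must lie inside a single cell of the same field; a nucleus
#' overlapping two cells (or background) violates the segmentation contract
#' and raises an error naming the labels involved.
#'
#' @param cells,nuclei Integer label matrices of identical shape.
#' @return Integer cytoplasm label matrix (same labels as `cells`).
#' @export
cytoplasm_mask <- function(cells, nuclei) {
  cells <- as.matrix(cells); nuclei <- as.matrix(nuclei)
  if (!all(dim(cells) == dim(nuclei)))
    stop_ms("cells and nuclei masks must have identical dimensions")
  nz <- nuclei > 0
  if (any(nz)) {
    pairs <- unique(cbind(nuc = nuclei[nz], cell = cells[nz]))
    bad <- names(which(table(pairs[, "nuc"]) > 1))
    if (length(bad) == 0 && any(pairs[, "cell"] == 0))
      bad <- unique(pairs[pairs[, "cell"] == 0, "nuc"])
    if (length(bad) > 0)
      stop_ms("nucleus label(s) %s span more than one cell label (or background)",
              paste(head(bad, 5), collapse = ", "))
  }
  cyto <- cells
  cyto[nz] <- 0L
  storage.mode(cyto) <- "integer"
  cyto
}
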