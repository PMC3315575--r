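# Synthetic confluent-monolayer scenes with per-cell ground truth.
#
# Geometry: cell centers are Poisson-disk sampled (dart throwing with a
# minimum spacing), then the field is tiled by the multiplicatively weighted
# Voronoi partition of the centers, which yields touching, convex-ish cells
# of varying size -- the flat confluent morphology the propagation
# segmentation is designed for. Each cell carries one circular nucleus and a
# clumped mitochondrial texture over its cytoplasm plus a small bleed term
# inside the nucleus footprint.

#' Generate one synthetic monolayer scene with ground truth
#'
#' Places cells as a weighted Voronoi tiling of Poisson-disk-sampled centers,
#' assigns each cell a nucleus and an integrated mitochondrial content drawn
#' around the coupling law `a * area^gamma` (modulated by the planted
#' effect), and renders noiseless nuclear, boundary (F-actin-like) and
#' mitochondrial rasters. Toxic effects binomially thin the tiling, leaving
#' background gaps where dead cells were.
#'
#' @param params A [scene_params] object.
#' @param effect An [effect_spec]; defaults to the null effect.
#' @param rng_seed Integer seed making the scene reproducible.
#' @return A list with elements `truth` (per-cell data frame: id, center,
#'   areas in px, true integrated content in AU, border flag), `rasters`
#'   (noiseless `nuclear`, `boundary`, `mito` matrices), `labels` (ground
#'   truth `cells` and `nuclei` label masks), `well_effect` (the per-well
#'   staining multiplier applied to the mito raster) and the inputs.
#' @export
generate_scene <- function(params, effect = effect_spec("null"), rng_seed = params$seed) {
  stopifnot(inherits(params, "scene_params"), inherits(effect, "effect_spec"))
  set.seed(rng_seed)
  H <- params$image_height_px; W <- params$image_width_px
  f <- effect$area_multiplier
  n_target <- max(0L, as.integer(round(params$target_cell_count / f)))

  empty <- function() {
    truth <- data.frame(cell_id = integer(), center_x = numeric(),
                        center_y = numeric(), weight_px = numeric(),
                        cell_area_px = integer(), nucleus_area_px = integer(),
                        cytoplasm_area_px = integer(), content_au = numeric(),
                        touches_border = logical())
    z <- matrix(0, H, W)
    list(truth = truth,
         rasters = list(nuclear = z, boundary = z, mito = z),
         labels = list(cells = matrix(0L, H, W), nuclei = matrix(0L, H, W)),
         well_effect = 1, params = params, effect = effect, rng_seed = rng_seed)
  }
  if (n_target == 0L) return(empty())

  # --- Poisson-disk centers (dart throwing) -------------------------------
  margin <- 6
  d_min <- 0.68 * sqrt(H * W / n_target)
  cx <- numeric(0); cy <- numeric(0)
  attempts <- 0L; max_attempts <- 400L * n_target
  while (length(cx) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    px <- runif(1, margin, W - 1 - margin)
    py <- runif(1, margin, H - 1 - margin)
    if (length(cx) == 0L || min((cx - px)^2 + (cy - py)^2) >= d_min^2) {
      cx <- c(cx, px); cy <- c(cy, py)
    }
  }
  if (length(cx) < n_target)
    stop_ms("impossible packing: placed %d of %d cells (min spacing %.1f px)",
            length(cx), n_target, d_min)

  # --- survival thinning (toxicity) --------------------------------------
  n_surv <- if (effect$survival_fraction < 1)
    rbinom(1L, n_target, effect$survival_fraction) else n_target
  alive <- sort(sample.int(n_target, n_surv))
  if (n_surv == 0L) return(empty())

  # --- weighted Voronoi tiling -------------------------------------------
  w_mean <- params$cell_radius_mean_px * sqrt(f)
  wts <- rnorm(n_target, w_mean, params$cell_radius_cv * w_mean)
  wts <- pmax(wts, 0.25 * w_mean)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)   # column index, 0-based
  ys <- matrix(rep(0:(H - 1), times = W), H, W)  # row index, 0-based
  best_d <- matrix(Inf, H, W)
  lab <- matrix(0L, H, W)
  for (i in seq_len(n_target)) {
    d2 <- ((xs - cx[i])^2 + (ys - cy[i])^2) / wts[i]^2
    upd <- d2 < best_d
    best_d[upd] <- d2[upd]
    lab[upd] <- i
  }
  lab[!(lab %in% alive)] <- 0L  # dead cells leave background gaps

  # --- nuclei -------------------------------------------------------------
  areas <- tabulate(lab, nbins = n_target)
  nuc <- matrix(0L, H, W)
  for (i in alive) {
    r_nuc <- params$nucleus_to_cell_radius_ratio * sqrt(areas[i] / pi)
    inside <- lab == i & ((xs - cx[i])^2 + (ys - cy[i])^2) <= r_nuc^2
    nuc[inside] <- i
  }

  # --- per-cell content under the coupling law ---------------------------
  gamma <- params$content_area_exponent
  mult <- effect$content_multiplier / f^gamma
  sdlog <- sqrt(log(1 + params$content_cv^2))
  lognoise <- exp(rnorm(n_target, -sdlog^2 / 2, sdlog))
  content <- params$content_scale * areas^gamma * mult * lognoise
  well_effect <- if (params$well_effect_cv > 0) {
    sl <- sqrt(log(1 + params$well_effect_cv^2))
    exp(rnorm(1, -sl^2 / 2, sl))
  } else 1

  # --- rasters ------------------------------------------------------------
  nuclear <- matrix(0, H, W)
  boundary <- matrix(0, H, W)
  mito <- matrix(0, H, W)

  # ridge pixels: 4-neighbour label change (image edge is not a ridge)
  ridge <- matrix(FALSE, H, W)
  ridge[-H, ] <- ridge[-H, ] | (lab[-H, ] != lab[-1, ])
  ridge[-1, ] <- ridge[-1, ] | (lab[-1, ] != lab[-H, ])
  ridge[, -W] <- ridge[, -W] | (lab[, -W] != lab[, -1])
  ridge[, -1] <- ridge[, -1] | (lab[, -1] != lab[, -W])

  clump_sigma <- 2.5
  for (i in alive) {
    cell_px <- which(lab == i)
    nuc_px <- which(nuc == i)
    cyto_px <- setdiff(cell_px, nuc_px)
    bright <- exp(rnorm(1, 0, 0.1))
    nuclear[nuc_px] <- 3000 * bright
    boundary[cell_px] <- 600 * exp(rnorm(1, 0, 0.1))
    boundary[nuc_px] <- 300 * bright
    # clumped mitochondrial texture over the cytoplasm
    tgt_cyto <- (1 - params$nuclear_bleed_fraction) * content[i] * well_effect
    if (length(cyto_px) > 0 && tgt_cyto > 0) {
      k <- max(2L, as.integer(round(length(cyto_px) / 70)))
      ctr <- cyto_px[sample.int(length(cyto_px), min(k, length(cyto_px)))]
      px_x <- xs[cyto_px]; px_y <- ys[cyto_px]
      dens <- rep(0.15, length(cyto_px))
      for (cp in ctr) {
        dens <- dens + exp(-((px_x - xs[cp])^2 + (px_y - ys[cp])^2) /
                             (2 * clump_sigma^2))
      }
      mito[cyto_px] <- mito[cyto_px] + dens / sum(dens) * tgt_cyto
    }
    if (length(nuc_px) > 0 && params$nuclear_bleed_fraction > 0) {
      mito[nuc_px] <- mito[nuc_px] +
        params$nuclear_bleed_fraction * content[i] * well_effect / length(nuc_px)
    }
  }
  # cortical F-actin ridges: strong contrast against the cytoplasm baseline,
  # the cue the propagation segmentation keys on
  boundary[ridge] <- 40000

  border_lab <- unique(c(lab[1, ], lab[H, ], lab[, 1], lab[, W]))
  nuc_areas <- tabulate(nuc, nbins = n_target)
  truth <- data.frame(
    cell_id = alive,
    center_x = cx[alive], center_y = cy[alive], weight_px = wts[alive],
    cell_area_px = areas[alive], nucleus_area_px = nuc_areas[alive],
    cytoplasm_area_px = areas[alive] - nuc_areas[alive],
    content_au = content[alive],
    touches_border = alive %in% border_lab)
  truth <- truth[truth$cell_area_px > 0, , drop = FALSE]

  list(truth = truth,
       rasters = list(nuclear = nuclear, boundary = boundary, mito = mito),
       labels = list(cells = lab, nuclei = nuc),
       well_effect = well_effect, params = params, effect = effect,
       rng_seed = rng_seed)
}

#' Smooth multiplicative illumination field
#'
#' Radial vignetting-style shading field with max/min ratio exactly
#' `1 + amplitude`, brightest at `center_frac` (fractions of height/width).
#'
#' @param height,width Field size in pixels.
#' @param amplitude Shading amplitude in `[0, 1)`.
#' @param center_frac Length-2 fraction (row, column) of the brightest point.
#' @return A `height x width` positive matrix with unit minimum 1 and maximum
#'   `1 + amplitude`.
#' @export
illumination_field <- function(height, width, amplitude,
                               center_frac = c(0.35, 0.6)) {
  if (amplitude == 0) return(matrix(1, height, width))
  cy <- center_frac[1] * (height - 1); cx <- center_frac[2] * (width - 1)
  ys <- matrix(rep(0:(height - 1), times = width), height, width)
  xs <- matrix(rep(0:(width - 1), each = height), height, width)
  r2 <- (ys - cy)^2 + (xs - cx)^2
  fshape <- 1 - r2 / max(r2)
  fshape <- (fshape - min(fshape)) / (max(fshape) - min(fshape))  # exactly [0, 1]
  1 + amplitude * fshape
}

#' Render noiseless rasters into corrupted channel images
#'
#' Applies, in order: Gaussian optical blur, the multiplicative illumination
#' field, Poisson shot noise (variance `poisson_scaling * intensity`),
#' additive Gaussian read noise, and clipping to the camera's bit depth.
#' With all corruption parameters zero the output equals the input raster.
#'
#' @param rasters Named list of noiseless matrices (`nuclear`, `boundary`,
#'   `mito`), e.g. the `rasters` element of [generate_scene()].
#' @param params A [scene_params].
#' @param rng_seed Seed for the noise draws.
#' @param illumination `NULL` (canonical field from
#'   `params$illumination_gradient_amplitude`), a single matrix, or a named
#'   per-channel list of matrices — pass the per-plate fields here so that
#'   all wells of one plate share the same shading, as the illumination
#'   correction assumes.
#' @param plate,well,site,day Identity attached to the output images.
#' @return Named list of three [channel_image] objects.
#' @export
render_channels <- function(rasters, params, rng_seed = params$seed,
                            illumination = NULL,
                            plate = "P1", well = "A01", site = 1L, day = 1L) {
  stopifnot(inherits(params, "scene_params"))
  channels <- c("nuclear", "boundary", "mito")
  if (!all(channels %in% names(rasters)))
    stop_ms("rasters must contain elements: %s", paste(channels, collapse = ", "))
  set.seed(rng_seed)
  H <- params$image_height_px; W <- params$image_width_px
  maxv <- 2^params$bit_depth - 1
  get_field <- function(ch) {
    if (is.null(illumination))
      return(illumination_field(H, W, params$illumination_gradient_amplitude))
    if (is.matrix(illumination)) return(illumination)
    illumination[[ch]] %||% stop_ms("no illumination field for channel %s", ch)
  }
  out <- lapply(channels, function(ch) {
    x <- rasters[[ch]]
    if (any(x < 0)) stop_ms("noiseless raster for %s has negative values", ch)
    if (params$blur_sigma_px > 0)
      x <- EBImage::gblur(x, sigma = params$blur_sigma_px)
    x <- x * get_field(ch)
    x <- pmax(x, 0)
    if (params$poisson_scaling > 0)
      x <- matrix(rpois(length(x), x / params$poisson_scaling) *
                    params$poisson_scaling, H, W)
    if (params$noise_gaussian_sd > 0)
      x <- x + matrix(rnorm(length(x), 0, params$noise_gaussian_sd), H, W)
    channel_image(clip(x, 0, maxv), channel = ch, plate = plate, well = well,
                  site = site, day = day)
  })
  names(out) <- channels
  out
}

#' Draw per-cell measurement records directly from the generative model
#'
#' Statistical fast path used for screen-scale simulations: samples the
#' same per-cell quantities the imaging chain would measure (cytoplasm area,
#' nucleus-masked integrated mitochondrial intensity, its area-normalized
#' value) from the scene model without rendering or segmenting pixels. Cell
#' areas are lognormal around the effect-scaled mean tiling area; content
#' follows the coupling law with the planted effect, per-cell lognormal
#' scatter and the per-well staining multiplier; the nuclear bleed fraction
#' is excluded, mirroring nucleus masking.
#'
#' @param params A [scene_params].
#' @param effect An [effect_spec].
#' @param rng_seed Integer seed.
#' @return Data frame of cell records (`cell_id`, areas in px,
#'   `integrated_mito_intensity_au`, `normalized_mito_intensity_au_per_px`,
#'   `touches_border` all `FALSE`).
#' @export
simulate_cell_records <- function(params, effect = effect_spec("null"),
                                  rng_seed = params$seed) {
  stopifnot(inherits(params, "scene_params"), inherits(effect, "effect_spec"))
  set.seed(rng_seed)
  f <- effect$area_multiplier
  n_target <- max(0L, as.integer(round(params$target_cell_count / f)))
  n <- if (effect$survival_fraction < 1)
    rbinom(1L, n_target, effect$survival_fraction) else n_target
  empty <- data.frame(cell_id = integer(), nucleus_area_px = numeric(),
                      cell_area_px = numeric(), cytoplasm_area_px = numeric(),
                      integrated_mito_intensity_au = numeric(),
                      normalized_mito_intensity_au_per_px = numeric(),
                      touches_border = logical())
  if (n == 0L) return(empty)
  # area scatter of the weighted Voronoi tiling, calibrated once against
  # rendered scenes (area CV ~ 2 x weight CV at the default packing)
  area_cv <- min(0.9, 2.0 * params$cell_radius_cv)
  mean_area <- params$image_height_px * params$image_width_px /
    max(params$target_cell_count, 1L) * f
  sdl <- sqrt(log(1 + area_cv^2))
  area <- exp(rnorm(n, log(mean_area) - sdl^2 / 2, sdl))
  nuc_area <- params$nucleus_to_cell_radius_ratio^2 * area
  cyto <- area - nuc_area
  gamma <- params$content_area_exponent
  sdc <- sqrt(log(1 + params$content_cv^2))
  content <- params$content_scale * area^gamma *
    (effect$content_multiplier / f^gamma) * exp(rnorm(n, -sdc^2 / 2, sdc))
  well_eff <- if (params$well_effect_cv > 0) {
    sl <- sqrt(log(1 + params$well_effect_cv^2))
    exp(rnorm(1, -sl^2 / 2, sl))
  } else 1
  integrated <- (1 - params$nuclear_bleed_fraction) * content * well_eff
  data.frame(cell_id = seq_len(n),
             nucleus_area_px = nuc_area,
             cell_area_px = area,
             cytoplasm_area_px = cyto,
             integrated_mito_intensity_au = integrated,
             normalized_mito_intensity_au_per_px = integrated / cyto,
             touches_border = FALSE)
}
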