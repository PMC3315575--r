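#' Scene parameters for the synthetic monolayer generator
#'
#' Bundles every knob of the synthetic imaging model: field geometry, cell
#' packing, the power-law coupling between cell area and mitochondrial
#' content, and the optical corruption model (blur, multiplicative
#' illumination gradient, Poisson-Gaussian noise). Defaults emulate a 20x
#' field of a confluent HUVEC-like monolayer in which a negative-control well
#' holds about 130 cells, so that the 40-cell toxicity cutoff sits at roughly
#' 30% of the control cell count.
#'
#' @param image_height_px,image_width_px Field size in pixels (>= 64).
#' @param target_cell_count Cells tiling a control field before any effect.
#' @param cell_radius_mean_px Mean equivalent cell radius in pixels; with the
#'   default field this packs ~130 touching cells.
#' @param cell_radius_cv Coefficient of variation of the per-cell Voronoi
#'   weight (drives cell-to-cell size scatter), in `[0, 1)`.
#' @param nucleus_to_cell_radius_ratio Nucleus radius as a fraction of the
#'   equivalent cell radius, in `(0, 1)`.
#' @param content_area_exponent Exponent `gamma` of the coupling law: expected
#'   integrated mitochondrial content is `content_scale * area^gamma` (AU).
#' @param content_scale Scale `a` of the coupling law, AU per px^gamma.
#' @param content_cv Per-cell lognormal scatter of content around the
#'   coupling law (biological cell-to-cell variability).
#' @param nuclear_bleed_fraction Fraction of a cell's mitochondrial signal
#'   rendered inside the nucleus footprint (residual dye accumulation that
#'   nucleus masking is meant to discount).
#' @param well_effect_cv Per-well multiplicative staining variability applied
#'   to the rendered mitochondrial channel (not to the ground-truth content).
#' @param noise_gaussian_sd Additive read-noise standard deviation, AU.
#' @param poisson_scaling Shot-noise gain: pixel variance is
#'   `poisson_scaling * intensity`. Zero disables shot noise.
#' @param blur_sigma_px Gaussian optical blur sigma in pixels.
#' @param illumination_gradient_amplitude Amplitude of the multiplicative
#'   shading field; its max/min ratio is `1 + amplitude`. In `[0, 1)`.
#' @param bit_depth Camera bit depth; intensities are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param seed Default RNG seed used when an operation is not given one.
#'
#' @return An object of class `scene_params` (a validated list).
#' @export
scene_params <- function(image_height_px = 256L,
                         image_width_px = 256L,
                         target_cell_count = 130L,
                         cell_radius_mean_px = 12,
                         cell_radius_cv = 0.25,
                         nucleus_to_cell_radius_ratio = 0.4,
                         content_area_exponent = 1,
                         content_scale = 60,
                         content_cv = 0.25,
                         nuclear_bleed_fraction = 0.08,
                         well_effect_cv = 0.03,
                         noise_gaussian_sd = 20,
                         poisson_scaling = 5,
                         blur_sigma_px = 1,
                         illumination_gradient_amplitude = 0.3,
                         bit_depth = 16L,
                         seed = 1L) {
  p <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    target_cell_count = as.integer(target_cell_count),
    cell_radius_mean_px = cell_radius_mean_px,
    cell_radius_cv = cell_radius_cv,
    nucleus_to_cell_radius_ratio = nucleus_to_cell_radius_ratio,
    content_area_exponent = content_area_exponent,
    content_scale = content_scale,
    content_cv = content_cv,
    nuclear_bleed_fraction = nuclear_bleed_fraction,
    well_effect_cv = well_effect_cv,
    noise_gaussian_sd = noise_gaussian_sd,
    poisson_scaling = poisson_scaling,
    blur_sigma_px = blur_sigma_px,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  )
  if (p$image_height_px < 64L || p$image_width_px < 64L)
    stop_ms("image dimensions must be >= 64 px (got %d x %d)",
            p$image_height_px, p$image_width_px)
  if (p$target_cell_count < 0L)
    stop_ms("target_cell_count must be >= 0")
  if (p$cell_radius_mean_px <= 0) stop_ms("cell_radius_mean_px must be > 0")
  if (p$cell_radius_cv < 0 || p$cell_radius_cv >= 1)
    stop_ms("cell_radius_cv must lie in [0, 1)")
  if (p$nucleus_to_cell_radius_ratio <= 0 || p$nucleus_to_cell_radius_ratio >= 1)
    stop_ms("nucleus_to_cell_radius_ratio must lie in (0, 1)")
  if (p$content_scale <= 0) stop_ms("content_scale must be > 0")
  if (p$content_cv < 0) stop_ms("content_cv must be >= 0")
  if (p$nuclear_bleed_fraction < 0 || p$nuclear_bleed_fraction >= 1)
    stop_ms("nuclear_bleed_fraction must lie in [0, 1)")
  if (p$noise_gaussian_sd < 0) stop_ms("noise_gaussian_sd must be >= 0")
  if (p$poisson_scaling < 0) stop_ms("poisson_scaling must be >= 0")
  if (p$blur_sigma_px < 0) stop_ms("blur_sigma_px must be >= 0")
  if (p$illumination_gradient_amplitude < 0 ||
      p$illumination_gradient_amplitude >= 1)
    stop_ms("illumination_gradient_amplitude must lie in [0, 1)")
  structure(p, class = "scene_params")
}

#' Planted compound-effect specification
#'
#' Describes how a compound perturbs the synthetic monolayer. In a confluent
#' field an area multiplier `f` is realised as roughly `target_cell_count/f`
#' cells tiling the same field (so mean cell area scales by `f`), and the
#' expected per-cell content is `a * area^gamma * content_multiplier /
#' f^gamma`. Under this construction:
#' * `null` leaves everything unchanged;
#' * `proportional` with content fold `m` uses `f = m^(1/gamma)` so total
#'   content and cell area both scale while the content/area ratio at
#'   `gamma = 1` is untouched (the stereotyped coupling the screen observes);
#' * `mito_only` / `mito_down` scale content only (`f = 1`), the dissociated
#'   phenotype the screen is designed to find;
#' * `toxic` thins the monolayer binomially by `survival_fraction`.
#'
#' @param effect_class One of `"null"`, `"proportional"`, `"mito_only"`,
#'   `"mito_down"`, `"toxic"`.
#' @param content_multiplier Fold change of expected per-cell content.
#' @param area_multiplier Fold change of mean cell area; derived
#'   automatically for `proportional` (from `gamma`) and forced to 1 for
#'   `mito_only`/`mito_down`.
#' @param survival_fraction Fraction of cells surviving treatment, `(0, 1]`.
#' @param gamma Coupling exponent used to derive the proportional-area
#'   multiplier; must match the scene's `content_area_exponent`.
#'
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(effect_class = c("null", "proportional", "mito_only",
                                         "mito_down", "toxic"),
                        content_multiplier = 1,
                        area_multiplier = NULL,
                        survival_fraction = 1,
                        gamma = 1) {
  effect_class <- match.arg(effect_class)
  if (content_multiplier <= 0) stop_ms("content_multiplier must be > 0")
  if (survival_fraction <= 0 || survival_fraction > 1)
    stop_ms("survival_fraction must lie in (0, 1]")
  if (effect_class == "null") {
    if (content_multiplier != 1 || (!is.null(area_multiplier) && area_multiplier != 1) ||
        survival_fraction != 1)
      stop_ms("null effect requires all multipliers equal to 1")
    area_multiplier <- 1
  } else if (effect_class == "proportional") {
    area_multiplier <- content_multiplier^(1 / gamma)
  } else if (effect_class %in% c("mito_only", "mito_down")) {
    if (!is.null(area_multiplier) && area_multiplier != 1)
      stop_ms("%s effect requires area_multiplier = 1", effect_class)
    if (effect_class == "mito_only" && content_multiplier < 1)
      stop_ms("mito_only expects content_multiplier >= 1")
    if (effect_class == "mito_down" && content_multiplier > 1)
      stop_ms("mito_down expects content_multiplier <= 1")
    area_multiplier <- 1
  } else if (effect_class == "toxic") {
    if (survival_fraction >= 1)
      stop_ms("toxic effect requires survival_fraction < 1")
    area_multiplier <- area_multiplier %||% 1
  }
  if (area_multiplier <= 0) stop_ms("area_multiplier must be > 0")
  structure(list(effect_class = effect_class,
                 content_multiplier = content_multiplier,
                 area_multiplier = area_multiplier,
                 survival_fraction = survival_fraction),
            class = "effect_spec")
}
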