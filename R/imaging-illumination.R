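# Retrospective illumination correction: per (plate, channel), the average
# image heavily smoothed, rescaled to unit mean, is the shading estimate.

#' Estimate a per-plate, per-channel illumination profile
#'
#' Averages all images sharing one (plate, channel), smooths the average with
#' a wide Gaussian so only slowly varying shading survives, rescales to unit
#' mean and floors the result at a small positive epsilon.
#'
#' @param images List of [channel_image]s from one plate and channel.
#' @param smoothing_scale_px Gaussian sigma of the smoothing; defaults to
#'   1/10 of the image width.
#' @param eps Positive floor for the profile.
#' @return An object of class `illumination_profile` with elements `profile`
#'   (unit-mean positive matrix), `plate`, `channel`, `n_images`.
#' @export
estimate_illumination <- function(images, smoothing_scale_px = NULL, eps = 1e-6) {
  if (length(images) < 1L) stop_ms("need at least one image")
  stopifnot(all(vapply(images, inherits, logical(1), "channel_image")))
  pl <- unique(vapply(images, function(x) x$plate, character(1)))
  ch <- unique(vapply(images, function(x) x$channel, character(1)))
  if (length(pl) != 1L || length(ch) != 1L)
    stop_ms("all images must share one (plate, channel); got plates [%s], channels [%s]",
            paste(pl, collapse = ","), paste(ch, collapse = ","))
  dims <- vapply(images, function(x) dim(x$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    bad <- vapply(images, function(x) x$well, character(1))[
      dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]]
    stop_ms("image shape mismatch in wells: %s", paste(bad, collapse = ", "))
  }
  avg <- Reduce(`+`, lapply(images, `[[`, "pixels")) / length(images)
  sigma <- smoothing_scale_px %||% (ncol(avg) / 10)
  smooth <- EBImage::gblur(avg, sigma = sigma, boundary = "replicate")
  smooth <- smooth / mean(smooth)
  structure(list(profile = pmax(smooth, eps), plate = pl, channel = ch,
                 smoothing_scale_px = sigma, n_images = length(images)),
            class = "illumination_profile")
}

#' Correct an image for uneven illumination
#'
#' Pixelwise division of the image by the (unit-mean) illumination profile of
#' its plate and channel.
#'
#' @param img A [channel_image].
#' @param profile An `illumination_profile` from [estimate_illumination()]
#'   with matching plate, channel and shape.
#' @return The corrected [channel_image].
#' @export
correct_illumination <- function(img, profile) {
  stopifnot(inherits(img, "channel_image"), inherits(profile, "illumination_profile"))
  if (img$plate != profile$plate || img$channel != profile$channel)
    stop_ms("profile (%s, %s) does not match image (%s, %s)",
            profile$plate, profile$channel, img$plate, img$channel)
  if (!all(dim(img$pixels) == dim(profile$profile)))
    stop_ms("profile shape %dx%d does not match image %dx%d",
            nrow(profile$profile), ncol(profile$profile),
            nrow(img$pixels), ncol(img$pixels))
  out <- img
  out$pixels <- img$pixels / profile$profile
  out
}
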