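#' Single-channel fluorescence image with acquisition identity
#'
#' Thin container pairing a 2-D nonnegative intensity matrix with the
#' identifiers the pipeline groups by (channel, plate, well, site, day).
#' Pixels are stored row-major with the origin at the top-left and 0-based
#' pixel coordinates in all reported measurements.
#'
#' @param pixels Numeric matrix of finite, nonnegative intensities.
#' @param channel One of `"nuclear"`, `"boundary"`, `"mito"`.
#' @param plate,well Plate and well identifiers.
#' @param site Imaging site within the well (the screen uses one per well).
#' @param day Screening day the well belongs to.
#'
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, channel = c("nuclear", "boundary", "mito"),
                          plate = "P1", well = "A01", site = 1L, day = 1L) {
  channel <- match.arg(channel)
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_ms("channel_image pixels must be finite and nonnegative")
  structure(list(pixels = pixels, channel = channel, plate = plate,
                 well = well, site = as.integer(site), day = as.integer(day)),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image %s %s_%s site %d day %d: %d x %d px, range [%.1f, %.1f]>\n",
              x$channel, x$plate, x$well, x$site, x$day,
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  invisible(x)
}

image_key <- function(img) paste(img$plate, img$well, img$site, img$channel, sep = "_")

#' Read and write single-channel 16-bit TIFF images
#'
#' Images are written as single-channel TIFFs named
#' `{plate}_{well}_{site}_{channel}.tif`. Intensities are stored as the
#' fraction of the bit-depth maximum (the `tiff` package convention) and
#' restored to AU on reading.
#'
#' @param img A [channel_image].
#' @param dir Directory to write to / read from.
#' @param bit_depth Camera bit depth used for scaling (default 16).
#' @param plate,well,site,channel Identity of the image to read (also parsed
#'   back from the file name).
#' @return `write_channel_image` returns the file path invisibly;
#'   `read_channel_image` returns a [channel_image].
#' @export
write_channel_image <- function(img, dir, bit_depth = 16L) {
  stopifnot(inherits(img, "channel_image"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s_%d_%s.tif", img$plate, img$well,
                                 img$site, img$channel))
  maxv <- 2^bit_depth - 1
  tiff::writeTIFF(clip(img$pixels / maxv, 0, 1), path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_channel_image
#' @param day Screening day to attach to the image read back (not encoded in
#'   the file name).
#' @export
read_channel_image <- function(dir, plate, well, site = 1L,
                               channel = c("nuclear", "boundary", "mito"),
                               day = 1L, bit_depth = 16L) {
  channel <- match.arg(channel)
  path <- file.path(dir, sprintf("%s_%s_%d_%s.tif", plate, well, as.integer(site), channel))
  if (!file.exists(path)) stop_ms("image file not found: %s", path)
  px <- tiff::readTIFF(path) * (2^bit_depth - 1)
  channel_image(px, channel = channel, plate = plate, well = well,
                site = site, day = day)
}
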