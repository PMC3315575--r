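# Multilevel (three-class) Otsu thresholding.
#
# The background cutoff for the mitochondrial channel is taken from a
# three-class Otsu split: the threshold pair (t_low, t_high) maximizing the
# between-class variance over three intensity classes. Whether the middle
# class counts as signal decides which of the two thresholds becomes the
# background cutoff.

#' Three-class Otsu thresholds
#'
#' Finds the bin pair `(t_low, t_high)` that maximizes the between-class
#' variance of the three classes it induces on the intensity histogram, and
#' derives the background cutoff from it. By default the middle class is
#' assigned to the foreground (cutoff = `t_low`), which preserves dim
#' mitochondrial signal.
#'
#' @param x Numeric vector/matrix of intensities, or `NULL` when a histogram
#'   is supplied directly.
#' @param n_bins Number of equal-width histogram bins when binning `x`.
#' @param counts Optional histogram counts (used instead of `x`).
#' @param bin_centers Optional bin center values accompanying `counts`;
#'   defaults to `seq_along(counts) - 1`.
#' @param middle_class_to `"foreground"` (default) or `"background"`.
#' @return List with `t_low`, `t_high` (threshold values: upper edges/centers
#'   of the chosen bins), `background_cutoff`, the maximized
#'   `between_class_variance`, and the chosen bin indices `i`, `j`.
#' @export
otsu_three_class <- function(x = NULL, n_bins = 128L, counts = NULL,
                             bin_centers = NULL,
                             middle_class_to = c("foreground", "background")) {
  middle_class_to <- match.arg(middle_class_to)
  if (is.null(counts)) {
    if (is.null(x)) stop_ms("supply intensities x or a histogram (counts)")
    x <- as.numeric(x)
    x <- x[is.finite(x)]
    if (length(unique(x)) < 3L)
      stop_ms("degenerate image: fewer than 3 distinct intensity values")
    rng <- range(x)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    idx <- clip(findInterval(x, breaks, rightmost.closed = TRUE), 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    bin_centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
    thr_values <- breaks[-1]  # threshold = upper edge of the last bin of a class
  } else {
    counts <- as.numeric(counts)
    if (is.null(bin_centers)) bin_centers <- seq_along(counts) - 1
    half <- if (length(bin_centers) > 1) median(diff(bin_centers)) / 2 else 0.5
    thr_values <- bin_centers + half  # threshold = upper edge of the bin
  }
  if (sum(counts > 0) < 3L)
    stop_ms("degenerate image: fewer than 3 occupied histogram bins")
  B <- length(counts)
  w <- counts / sum(counts)
  cw <- cumsum(w)
  cm <- cumsum(w * bin_centers)
  mu <- cm[B]
  # all pairs 1 <= i < j < B: class1 = bins 1..i, class2 = i+1..j, class3 = j+1..B
  ij <- which(upper.tri(matrix(TRUE, B, B)), arr.ind = TRUE)
  ij <- ij[ij[, 2] < B, , drop = FALSE]
  i <- ij[, 1]; j <- ij[, 2]
  w1 <- cw[i];            m1 <- cm[i]
  w2 <- cw[j] - cw[i];    m2 <- cm[j] - cm[i]
  w3 <- 1 - cw[j];        m3 <- mu - cm[j]
  # between-class variance sum_k w_k (mu_k - mu)^2 = sum_k m_k^2 / w_k - mu^2
  term <- function(m, wgt) ifelse(wgt > 0, m^2 / wgt, 0)
  bcv <- term(m1, w1) + term(m2, w2) + term(m3, w3) - mu^2
  best <- which.max(bcv)  # deterministic: first maximum in (i, j) order
  t_low <- thr_values[i[best]]
  t_high <- thr_values[j[best]]
  list(t_low = t_low, t_high = t_high,
       background_cutoff = if (middle_class_to == "foreground") t_low else t_high,
       between_class_variance = bcv[best],
       i = i[best], j = j[best])
}

# Two-class Otsu on an intensity matrix via EBImage, returning a cutoff in AU.
otsu_two_class <- function(x, levels = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(EBImage::Image(x), range = rng, levels = levels)
}
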