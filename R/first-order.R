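# First-order (histogram) statistics of a quantized ROI.

#' First-order statistics
#'
#' Six histogram features of the in-mask quantized levels: mean, variance
#' (population), skewness, kurtosis (non-excess; both defined as 0 for a
#' degenerate distribution), energy (sum of squared level probabilities)
#' and entropy (bits over the B levels).
#'
#' @param roi A [quantized_roi()], or a numeric matrix plus `mask`.
#' @param mask Optional logical mask when `roi` is a bare matrix (values
#'   are then quantized to `n_levels` first).
#' @param n_levels Levels used when quantizing a bare matrix (default 8).
#' @return Named numeric vector of 6 features.
#' @export
first_order_stats <- function(roi, mask = NULL, n_levels = 8) {
  if (!inherits(roi, "quantized_roi")) {
    if (is.null(mask)) stop("mask required for a bare matrix")
    roi <- normalize_quantize(roi, mask, n_levels)
  }
  x <- roi$levels[roi$mask]
  if (length(x) == 0) stop("mask is empty")
  n <- length(x)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v < 1e-12) {
    skew <- 0; kurt <- 0
  } else {
    skew <- mean((x - m)^3) / v^1.5
    kurt <- mean((x - m)^4) / v^2
  }
  p <- tabulate(x, nbins = roi$n_levels) / n
  nz <- p[p > 0]
  c(fos_mean = m, fos_variance = v, fos_skewness = skew,
    fos_kurtosis = kurt, fos_energy = sum(p^2),
    fos_entropy = -sum(nz * log2(nz)))
}
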