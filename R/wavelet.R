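# Single-level 2-D Daubechies (db2) wavelet decomposition and the
# per-subband texture features computed from it.

db2_filters <- function() {
  s3 <- sqrt(3)
  lo <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  hi <- c(lo[4], -lo[3], lo[2], -lo[1])  # quadrature mirror
  list(lo = lo, hi = hi)
}

# Filter the columns of `mat` with the 4-tap filter `f` under symmetric
# boundary extension, then downsample by 2 (even phase).
conv_ds_cols <- function(mat, f) {
  n <- nrow(mat)
  p <- 3L
  ext <- rbind(mat[p:1, , drop = FALSE], mat, mat[n:(n - p + 1), , drop = FALSE])
  m <- n + p
  y <- f[1] * ext[1:m, , drop = FALSE] +
       f[2] * ext[2:(m + 1), , drop = FALSE] +
       f[3] * ext[3:(m + 2), , drop = FALSE] +
       f[4] * ext[4:(m + 3), , drop = FALSE]
  y[seq(2, m, by = 2), , drop = FALSE]
}

conv_ds_rows <- function(mat, f) t(conv_ds_cols(t(mat), f))

#' Single-level db2 2-D discrete wavelet transform
#'
#' @param mat Numeric matrix, at least 4 x 4.
#' @return List of subband matrices `LL`, `LH`, `HL`, `HH` (LH = lowpass
#'   rows / highpass columns).
#' @export
dwt2_db2 <- function(mat) {
  if (nrow(mat) < 4 || ncol(mat) < 4)
    stop("wavelet decomposition needs a bounding box of at least 4 x 4")
  f <- db2_filters()
  lo_c <- conv_ds_cols(mat, f$lo)
  hi_c <- conv_ds_cols(mat, f$hi)
  list(LL = conv_ds_rows(lo_c, f$lo),
       LH = conv_ds_rows(hi_c, f$lo),
       HL = conv_ds_rows(lo_c, f$hi),
       HH = conv_ds_rows(hi_c, f$hi))
}

# Nearest-neighbor downsampling of the mask onto the subband grid.
downsample_mask <- function(mask, nr_out, nc_out) {
  ri <- pmin(2 * seq_len(nr_out) - 1, nrow(mask))
  ci <- pmin(2 * seq_len(nc_out) - 1, ncol(mask))
  mask[ri, ci, drop = FALSE]
}

# FoS + GLCM + GLRLM (19) on the re-quantized subband, plus the three
# subband summaries (relative energy filled in by the caller).
subband_features <- function(sub, mask_ds, n_levels = 8) {
  if (!any(mask_ds)) mask_ds <- matrix(TRUE, nrow(sub), ncol(sub))
  roi <- normalize_quantize(sub, mask_ds, n_levels)
  energy <- sum(sub[mask_ds]^2)
  list(features = c(first_order_stats(roi),
                    glcm_features(roi),
                    glrlm_features(roi)),
       energy = energy,
       log_energy = log(energy + 1e-12),
       mean_abs = mean(abs(sub[mask_ds])))
}

#' Wavelet-domain texture features (88 values)
#'
#' Applies a single-level db2 decomposition to the ROI bounding-box image
#' and, for each of the four subbands (LL, LH, HL, HH, in that order),
#' computes FoS (6), direction-averaged GLCM (6) and GLRLM (7) features
#' on the re-normalized, 8-level re-quantized subband restricted to the
#' nearest-neighbor-downsampled mask, plus three subband summaries:
#' relative energy (the four sum to 1), log-energy, and mean absolute
#' coefficient. 22 features x 4 subbands = 88.
#'
#' @param slice An [image_slice()] or numeric matrix.
#' @param mask Logical matrix, nonempty; bounding box must be >= 4 x 4.
#' @param n_levels Quantization levels per subband (default 8).
#' @return Named numeric vector of 88 features.
#' @export
wavelet_features <- function(slice, mask, n_levels = 8) {
  px <- if (inherits(slice, "image_slice")) slice$pixels else as.matrix(slice)
  mask <- mask > 0.5
  if (!any(mask)) stop("mask is empty")
  cr <- crop_to_bbox(px, mask)
  if (nrow(cr$mat) < 4 || ncol(cr$mat) < 4)
    stop("ROI bounding box smaller than 4 x 4: wavelet block undefined")
  bands <- dwt2_db2(cr$mat)
  subs <- lapply(bands, function(s)
    subband_features(s, downsample_mask(cr$mask, nrow(s), ncol(s)), n_levels))
  total_energy <- sum(vapply(subs, `[[`, numeric(1), "energy"))
  out <- numeric(0)
  for (nm in c("LL", "LH", "HL", "HH")) {
    sb <- subs[[nm]]
    rel <- if (total_energy > 0) sb$energy / total_energy
           else if (nm == "LL") 1 else 0
    block <- c(sb$features, rel_energy = rel,
               log_energy = sb$log_energy, mean_abs = sb$mean_abs)
    names(block) <- paste0("wav_", nm, "_", names(block))
    out <- c(out, block)
  }
  out
}
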