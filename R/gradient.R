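# Gradient-domain texture features (Sobel magnitude image).

# 3x3 convolution with symmetric boundary extension.
conv3x3 <- function(mat, k) {
  nr <- nrow(mat); nc <- ncol(mat)
  ext <- rbind(mat[1, , drop = FALSE], mat, mat[nr, , drop = FALSE])
  ext <- cbind(ext[, 1, drop = FALSE], ext, ext[, nc, drop = FALSE])
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    w <- k[dr + 2, dc + 2]
    if (w != 0)
      out <- out + w * ext[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

#' Sobel gradient-magnitude image
#'
#' @param mat Numeric matrix.
#' @return Matrix of the same shape: sqrt(Gx^2 + Gy^2).
#' @export
sobel_magnitude <- function(mat) {
  kx <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  ky <- t(kx)
  sqrt(conv3x3(mat, kx)^2 + conv3x3(mat, ky)^2)
}

#' Gradient-domain texture features (19 values)
#'
#' Computes the Sobel gradient-magnitude image of the ROI, then FoS (6),
#' direction-averaged GLCM (6) and GLRLM (7) features on the
#' re-normalized, 8-level re-quantized magnitude image within the mask
#' eroded by one pixel (the Sobel window is undefined on the mask rim).
#'
#' @param slice An [image_slice()] or numeric matrix.
#' @param mask Logical matrix, nonempty.
#' @param n_levels Quantization levels (default 8).
#' @return Named numeric vector of 19 features.
#' @export
gradient_features <- function(slice, mask, n_levels = 8) {
  px <- if (inherits(slice, "image_slice")) slice$pixels else as.matrix(slice)
  mask <- mask > 0.5
  if (!any(mask)) stop("mask is empty")
  mag <- sobel_magnitude(px)
  core <- erode3x3(mask)
  if (!any(core)) stop("mask erodes to empty: gradient block undefined")
  roi <- normalize_quantize(mag, core, n_levels)
  out <- tryCatch(
    c(first_order_stats(roi), glcm_features(roi), glrlm_features(roi)),
    error = function(e) {
      # eroded core left only isolated pixels (no co-occurring pair in
      # any direction): fall back to the full mask for this block
      roi <- normalize_quantize(mag, mask, n_levels)
      c(first_order_stats(roi), glcm_features(roi), glrlm_features(roi))
    })
  names(out) <- paste0("grad_", names(out))
  out
}
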