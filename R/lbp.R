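# Rotation-invariant uniform local binary patterns (P = 8, R = 1).

#' LBP histogram features
#'
#' Computes riu2 LBP codes (8 neighbors, radius 1, neighbor >= center
#' comparison) on the min-max-normalized continuous image, over in-mask
#' pixels whose full 8-neighborhood lies in the mask, and returns the
#' normalized 10-bin histogram (codes 0-8 plus the non-uniform bin).
#'
#' @param slice An [image_slice()] or numeric matrix.
#' @param mask Logical matrix, nonempty.
#' @return Named numeric vector of 10 histogram proportions (sums to 1).
#' @export
lbp_features <- function(slice, mask) {
  px <- if (inherits(slice, "image_slice")) slice$pixels else as.matrix(slice)
  mask <- mask > 0.5
  if (!any(mask)) stop("mask is empty")
  x <- px[mask]
  rng <- range(x)
  norm <- px
  if (rng[2] > rng[1]) norm <- (px - rng[1]) / (rng[2] - rng[1])
  codes <- cpp_lbp_codes(norm, mask)
  valid <- codes[codes >= 0]
  if (length(valid) == 0)
    stop("no in-mask pixel with a full 8-neighborhood")
  h <- tabulate(valid + 1L, nbins = 10L) / length(valid)
  names(h) <- c(paste0("lbp_u", 0:8), "lbp_nonuniform")
  h
}
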