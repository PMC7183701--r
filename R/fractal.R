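# Box-counting fractal dimension.

#' Box-counting dimension of a binary set
#'
#' Counts occupied boxes at dyadic box sizes (1, 2, 4, ... up to half the
#' larger grid dimension) and returns the least-squares slope of
#' log N(s) versus log(1/s). If fewer than 2 boxes are occupied at the
#' coarsest scale the set is too sparse for a slope and 0 is returned
#' with a warning.
#'
#' @param set Logical matrix: the binarized texture (TRUE = occupied).
#' @return Estimated dimension (scalar).
#' @export
box_counting_dimension <- function(set) {
  set <- set > 0.5
  if (!any(set)) {
    warning("empty set: box-counting dimension undefined, returning 0")
    return(0)
  }
  nmax <- max(dim(set))
  sizes <- 1L
  while (sizes[length(sizes)] * 2 <= nmax / 2)
    sizes <- c(sizes, sizes[length(sizes)] * 2L)
  idx <- which(set, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    key <- ((idx[, 1] - 1L) %/% s) * (nmax + 1) + (idx[, 2] - 1L) %/% s
    length(unique(key))
  }, numeric(1))
  if (counts[length(counts)] < 2) {
    warning("fewer than 2 occupied boxes at the coarsest scale; returning 0")
    return(0)
  }
  unname(coef(lm(log(counts) ~ log(1 / sizes)))[2])
}

#' Fractal dimension of an ROI's texture
#'
#' Thresholds the min-max-normalized ROI at its in-mask median (strictly
#' above) and applies [box_counting_dimension()] to the resulting set.
#'
#' @param slice An [image_slice()] or numeric matrix.
#' @param mask Logical matrix, nonempty.
#' @return Estimated dimension (scalar).
#' @export
fractal_dimension <- function(slice, mask) {
  px <- if (inherits(slice, "image_slice")) slice$pixels else as.matrix(slice)
  mask <- mask > 0.5
  if (!any(mask)) stop("mask is empty")
  x <- px[mask]
  med <- median(x)
  set <- matrix(FALSE, nrow(px), ncol(px))
  set[mask] <- x > med
  box_counting_dimension(set)
}
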