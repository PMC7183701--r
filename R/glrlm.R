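# Gray-level run-length matrices and Galloway-style features.

#' Gray-level run-length matrix
#'
#' Runs are maximal constant-level segments along the direction, truncated
#' at the mask boundary; entry (i, r) counts runs of level i and length r.
#'
#' @param roi A [quantized_roi()].
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @return A `glrl_matrix`: B x Rmax count matrix with attribute
#'   `direction`.
#' @export
glrlm <- function(roi, direction = 0) {
  stopifnot(inherits(roi, "quantized_roi"))
  if (!any(roi$mask)) stop("mask is empty")
  off <- direction_offset(direction, 1)
  lev <- roi$levels
  lev[is.na(lev)] <- 0L
  maxrun <- max(dim(lev))
  counts <- cpp_glrlm_counts(lev, roi$mask, off[1], off[2],
                             roi$n_levels, maxrun)
  structure(counts, direction = direction,
            class = c("glrl_matrix", "matrix"))
}

# The seven per-matrix features, in canonical order.
# n_pixels = in-mask pixels covered by runs (equals total in-mask pixels).
glrlm_features_one <- function(m) {
  b <- nrow(m); rmax <- ncol(m)
  r <- matrix(seq_len(rmax), b, rmax, byrow = TRUE)
  i <- matrix(seq_len(b), b, rmax)
  n_runs <- sum(m)
  n_pix <- sum(m * r)
  if (n_runs == 0) stop("empty run-length matrix")
  c(glrlm_sre = sum(m / r^2) / n_runs,
    glrlm_lre = sum(m * r^2) / n_runs,
    glrlm_gln = sum(rowSums(m)^2) / n_runs,
    glrlm_rp = n_runs / n_pix,
    glrlm_rln = sum(colSums(m)^2) / n_runs,
    glrlm_lglre = sum(m / i^2) / n_runs,
    glrlm_hglre = sum(m * i^2) / n_runs)
}

#' Direction-averaged GLRLM features
#'
#' Features \{SRE, LRE, GLN, RP, RLN, LGLRE, HGLRE\} computed for each of
#' the four directions and averaged. RP is (number of runs)/(number of
#' in-mask pixels).
#'
#' @param matrices List of `glrl_matrix`, or a [quantized_roi()] (all four
#'   directions are computed).
#' @return Named numeric vector of 7 features.
#' @export
glrlm_features <- function(matrices) {
  if (inherits(matrices, "quantized_roi"))
    matrices <- lapply(c(0, 45, 90, 135), function(d) glrlm(matrices, d))
  rowMeans(vapply(matrices, glrlm_features_one, numeric(7)))
}
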