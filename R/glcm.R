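# Gray-level co-occurrence matrices and Haralick-style features.

# direction in degrees -> (dr, dc) offset at unit distance
direction_offset <- function(direction, distance = 1) {
  off <- switch(as.character(direction),
                "0"   = c(0L, 1L),
                "45"  = c(-1L, 1L),
                "90"  = c(-1L, 0L),
                "135" = c(-1L, -1L),
                stop("direction must be one of 0, 45, 90, 135"))
  off * as.integer(distance)
}

#' Gray-level co-occurrence matrix
#'
#' Counts in-mask level pairs at the given offset, symmetrizes (each pair
#' counted in both orders), and normalizes to sum 1.
#'
#' @param roi A [quantized_roi()].
#' @param direction One of 0, 45, 90, 135 (degrees).
#' @param distance Offset length in pixels (default 1).
#' @param symmetric Count each pair in both orders (default TRUE).
#' @param normalize Normalize to probabilities (default TRUE).
#' @return A `glc_matrix`: B x B matrix with attributes `direction`,
#'   `distance`, `symmetric`, `normalized`.
#' @export
glcm <- function(roi, direction = 0, distance = 1, symmetric = TRUE,
                 normalize = TRUE) {
  stopifnot(inherits(roi, "quantized_roi"), distance >= 1)
  off <- direction_offset(direction, distance)
  lev <- roi$levels
  lev[is.na(lev)] <- 0L
  counts <- cpp_glcm_counts(lev, roi$mask, off[1], off[2], roi$n_levels)
  if (symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot == 0)
    stop("no co-occurring in-mask pair in direction ", direction)
  if (normalize) counts <- counts / tot
  structure(counts, direction = direction, distance = distance,
            symmetric = symmetric, normalized = normalize,
            class = c("glc_matrix", "matrix"))
}

# All four standard directions; directions with no valid pair come back
# as NULL and are excluded from the feature average.
glcm_all_directions <- function(roi, distance = 1) {
  lapply(c(0, 45, 90, 135), function(d) {
    tryCatch(glcm(roi, d, distance), error = function(e) NULL)
  })
}

# The six per-matrix features, in canonical order.
glcm_features_one <- function(p) {
  b <- nrow(p)
  i <- matrix(seq_len(b), b, b)
  j <- t(i)
  energy <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p)); sd_j <- sqrt(sum((j - mu_j)^2 * p))
  correlation <- if (sd_i * sd_j < 1e-12) 1 else
    (sum(i * j * p) - mu_i * mu_j) / (sd_i * sd_j)
  homogeneity <- sum(p / (1 + abs(i - j)))
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  dissimilarity <- sum(abs(i - j) * p)
  c(glcm_energy = energy, glcm_contrast = contrast,
    glcm_correlation = correlation, glcm_homogeneity = homogeneity,
    glcm_entropy = entropy, glcm_dissimilarity = dissimilarity)
}

#' Direction-averaged GLCM features
#'
#' Features \{energy, contrast, correlation, homogeneity, entropy (bits),
#' dissimilarity\} computed per direction matrix and averaged; directions
#' without a single valid pair are excluded from the average.
#'
#' @param matrices List of `glc_matrix` (entries may be NULL), or a
#'   [quantized_roi()] (all four directions are computed).
#' @param distance Offset distance when a ROI is given.
#' @return Named numeric vector of 6 features.
#' @export
glcm_features <- function(matrices, distance = 1) {
  if (inherits(matrices, "quantized_roi"))
    matrices <- glcm_all_directions(matrices, distance)
  matrices <- Filter(Negate(is.null), matrices)
  if (length(matrices) == 0) stop("no direction with a valid pair")
  rowMeans(vapply(matrices, glcm_features_one, numeric(6)))
}
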