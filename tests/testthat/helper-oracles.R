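# Brute-force oracles, independent of the package's implementations.

# Naive co-occurrence: loop over every pixel pair at the offset,
# symmetrize, normalize.
oracle_glcm <- function(levels, mask, dr, dc) {
  b <- max(levels[mask])
  out <- matrix(0, b, b)
  nr <- nrow(levels); nc <- ncol(levels)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    i2 <- i + dr; j2 <- j + dc
    if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc || !mask[i2, j2]) next
    out[levels[i, j], levels[i2, j2]] <- out[levels[i, j], levels[i2, j2]] + 1
  }
  out <- out + t(out)
  out / sum(out)
}

# Naive run enumeration: walk every line in the direction, rle the
# in-mask segments.
oracle_glrlm <- function(levels, mask, dr, dc, n_levels, maxrun) {
  nr <- nrow(levels); nc <- ncol(levels)
  out <- matrix(0, n_levels, maxrun)
  visited <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || visited[i, j]) next
    # walk back to the run-line start
    r <- i; c <- j
    while (r - dr >= 1 && r - dr <= nr && c - dc >= 1 && c - dc <= nc &&
           mask[r - dr, c - dc]) { r <- r - dr; c <- c - dc }
    # collect the whole in-mask segment from here
    vals <- c()
    while (r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]) {
      vals <- c(vals, levels[r, c])
      visited[r, c] <- TRUE
      r <- r + dr; c <- c + dc
    }
    runs <- rle(vals)
    for (k in seq_along(runs$lengths))
      out[runs$values[k], min(runs$lengths[k], maxrun)] <-
        out[runs$values[k], min(runs$lengths[k], maxrun)] + 1
  }
  out
}

oracle_glcm_contrast <- function(p) {
  b <- nrow(p)
  sum(outer(1:b, 1:b, function(i, j) (i - j)^2) * p)
}

# Per-pixel riu2 LBP code by direct comparison (NA if neighborhood
# incomplete).
oracle_lbp_code <- function(img, mask, i, j) {
  nr <- nrow(img); nc <- ncol(img)
  if (i <= 1 || j <= 1 || i >= nr || j >= nc) return(NA_integer_)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  if (!mask[i, j]) return(NA_integer_)
  bits <- integer(8)
  for (k in 1:8) {
    if (!mask[i + dr[k], j + dc[k]]) return(NA_integer_)
    bits[k] <- as.integer(img[i + dr[k], j + dc[k]] >= img[i, j])
  }
  trans <- sum(bits != bits[c(2:8, 1)])
  if (trans <= 2) sum(bits) else 9L
}

# AUC by exhaustive positive-negative pair counting (ties = 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# A random quantized ROI for property loops.
random_roi <- function(nr = 9, nc = 9, n_levels = 8, p_mask = 0.85) {
  vals <- matrix(rnorm(nr * nc), nr, nc)
  mask <- matrix(runif(nr * nc) < p_mask, nr, nc)
  if (!any(mask)) mask[1, 1] <- TRUE
  normalize_quantize(vals, mask, n_levels)
}
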