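# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive reproducible per-item sub-seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Mean and SD of a normal truncated below at `lower`.
truncnorm_moments <- function(mu, sigma, lower) {
  a <- (lower - mu) / sigma
  z <- 1 - pnorm(a)
  lam <- dnorm(a) / z
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) such that the truncated-below-at-`lower` normal has the
# requested mean and SD (moment matching by Nelder-Mead).
truncnorm_match <- function(target_mean, target_sd, lower) {
  stopifnot(target_mean > lower, target_sd > 0)
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lower)
    (mm[1] - target_mean)^2 + (mm[2] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Inverse-CDF sampler for the truncated normal (consumes n uniforms).
rtruncnorm_lower <- function(n, mu, sigma, lower) {
  plo <- pnorm((lower - mu) / sigma)
  u <- runif(n, plo, 1)
  mu + sigma * qnorm(u)
}

# Erode a logical mask with a 3x3 (8-connected) structuring element.
erode3x3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mask
  for (dr in -1:1) for (dc in -1:1) {
    out <- out & padded[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

# Bounding box (row/col ranges) of a nonempty logical mask.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty")
  list(rows = range(idx[, 1]), cols = range(idx[, 2]))
}

crop_to_bbox <- function(mat, mask, pad = 0L) {
  bb <- mask_bbox(mask)
  r <- c(max(1L, bb$rows[1] - pad), min(nrow(mat), bb$rows[2] + pad))
  cl <- c(max(1L, bb$cols[1] - pad), min(ncol(mat), bb$cols[2] + pad))
  list(mat = mat[r[1]:r[2], cl[1]:cl[2], drop = FALSE],
       mask = mask[r[1]:r[2], cl[1]:cl[2], drop = FALSE])
}
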