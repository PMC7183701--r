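# Shape descriptors of a binary ROI mask.

# Largest 8-connected component of a mask.
largest_component <- function(mask) cpp_largest_component(mask)

# Ordered boundary pixels by Moore-neighbor tracing (clockwise scan
# starting after the background backtrack pixel), stopping when the start
# pixel is re-entered towards the same successor.
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  inm <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  idx <- which(mask, arr.ind = TRUE)
  o <- order(idx[, 1], idx[, 2])
  start <- as.integer(idx[o[1], ])  # topmost, then leftmost
  # Moore neighborhood, clockwise starting from "up"
  moves <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                 c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  cur <- start
  back <- start + c(-1L, 0L)  # entered from above (background by choice)
  boundary <- matrix(start, 1, 2)
  first_move <- NULL
  max_iter <- 8L * sum(mask) + 8L
  for (iter in seq_len(max_iter)) {
    rel <- back - cur
    bi <- which(moves[, 1] == rel[1] & moves[, 2] == rel[2])
    nxt <- NULL
    for (k in 1:8) {
      d <- ((bi - 1L + k) %% 8L) + 1L
      cand <- cur + moves[d, ]
      if (inm(cand[1], cand[2])) {
        nxt <- cand
        new_back <- cur + moves[((d - 2L) %% 8L) + 1L, ]
        break
      }
    }
    if (is.null(nxt)) return(boundary)  # isolated pixel
    if (all(cur == start)) {
      if (!is.null(first_move) && all(nxt == first_move)) break
      if (is.null(first_move)) first_move <- nxt
    }
    boundary <- rbind(boundary, nxt)
    back <- new_back
    cur <- nxt
  }
  # drop the duplicate start appended on closure, if present
  if (nrow(boundary) > 1 && all(boundary[nrow(boundary), ] == start))
    boundary <- boundary[-nrow(boundary), , drop = FALSE]
  boundary
}

# Perimeter by corrected chain code (Vossepoel-Smeulders weights).
mask_perimeter <- function(mask, spacing = 1) {
  n <- sum(mask)
  if (n == 1) return(4 * spacing)
  b <- trace_boundary(mask)
  if (nrow(b) < 2) return(4 * spacing * sqrt(n))
  steps <- rbind(diff(b), b[1, ] - b[nrow(b), ])
  keep <- abs(steps[, 1]) + abs(steps[, 2]) > 0
  steps <- steps[keep, , drop = FALSE]
  diag_step <- abs(steps[, 1]) + abs(steps[, 2]) == 2
  (0.948 * sum(!diag_step) + 1.340 * sum(diag_step)) * spacing
}

#' Shape features of an ROI mask
#'
#' Nine descriptors of the (largest connected component of the) mask:
#' area (mm^2), perimeter (mm, corrected chain code), major- and
#' minor-axis lengths (mm, from second-order image moments, i.e. the axes
#' of the moment-equivalent ellipse), eccentricity, solidity (area /
#' convex-hull area), extent (area / bounding-box area), equivalent
#' diameter (mm), and circularity 4*pi*A/P^2.
#'
#' @param mask Logical matrix, nonempty.
#' @param spacing Pixel spacing in mm (isotropic).
#' @return Named numeric vector of 9 features.
#' @export
shape_features <- function(mask, spacing = 1) {
  mask <- mask > 0.5
  if (!any(mask)) stop("mask is empty")
  mask <- largest_component(mask)
  n <- sum(mask)
  area <- n * spacing^2
  perim <- mask_perimeter(mask, spacing)

  pts <- which(mask, arr.ind = TRUE)
  if (n >= 2) {
    cc <- stats::cov(pts) * (n - 1) / n  # population covariance
    ev <- eigen(cc, symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    major <- 4 * sqrt(ev[1]) * spacing
    minor <- 4 * sqrt(ev[2]) * spacing
  } else {
    major <- spacing; minor <- spacing
  }
  if (major < minor) { tmp <- major; major <- minor; minor <- tmp }
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0

  # solidity: pixel count / rasterized convex-hull pixel count (the
  # hull of in-mask pixel centers, dilated by an epsilon so boundary
  # pixels count as inside)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hull_area <- if (length(hull) >= 3) {
    hp <- pts[hull, , drop = FALSE]
    ctr_h <- colMeans(hp)
    vy <- ctr_h[1] + (hp[, 1] - ctr_h[1]) * (1 + 1e-9)
    vx <- ctr_h[2] + (hp[, 2] - ctr_h[2]) * (1 + 1e-9)
    bb0 <- mask_bbox(mask)
    grid <- expand.grid(row = bb0$rows[1]:bb0$rows[2],
                        col = bb0$cols[1]:bb0$cols[2])
    inside <- rep(FALSE, nrow(grid))
    jprev <- length(vx)
    for (k in seq_along(vx)) {
      crosses <- (vy[k] > grid$row) != (vy[jprev] > grid$row)
      xi <- (vx[jprev] - vx[k]) * (grid$row - vy[k]) /
        (vy[jprev] - vy[k]) + vx[k]
      inside <- xor(inside, crosses & (grid$col < xi))
      jprev <- k
    }
    sum(inside) * spacing^2
  } else area
  solidity <- min(area / max(hull_area, area), 1)

  bb <- mask_bbox(mask)
  bbox_area <- (diff(bb$rows) + 1) * (diff(bb$cols) + 1) * spacing^2
  extent <- area / bbox_area
  eq_diam <- 2 * sqrt(area / pi)
  circ <- 4 * pi * area / perim^2

  c(shape_area = area, shape_perimeter = perim,
    shape_major_axis = major, shape_minor_axis = minor,
    shape_eccentricity = ecc, shape_solidity = solidity,
    shape_extent = extent, shape_equiv_diameter = eq_diam,
    shape_circularity = circ)
}
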