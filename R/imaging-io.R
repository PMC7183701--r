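# Image/mask IO, resampling, slice selection, and quantization.

#' Construct an image slice
#'
#' @param pixels 2-D numeric matrix of intensities (finite).
#' @param spacing Pixel spacing in mm, recycled to (row, col).
#' @return An `image_slice` object.
#' @export
image_slice <- function(pixels, spacing = c(1, 1)) {
  pixels <- as.matrix(pixels)
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  if (any(spacing <= 0)) stop("spacing must be > 0 in both axes")
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  structure(list(pixels = pixels, spacing = as.numeric(spacing)),
            class = "image_slice")
}

#' Resample a slice in-plane to a target spacing
#'
#' Cubic-spline interpolation applied separably (rows, then columns);
#' cubic splines reproduce polynomials up to degree 3, so linear ramps
#' pass through exactly. The physical extent is preserved to within one
#' output pixel. An input already at the target spacing is returned
#' unchanged. Use `method = "nearest"` for binary masks.
#'
#' @param slice An [image_slice()] (a bare matrix is accepted and assumed
#'   at `spacing`).
#' @param target_spacing Output spacing in mm (default 1).
#' @param method `"bspline"` (cubic) or `"nearest"`.
#' @return An [image_slice()] at the target spacing.
#' @export
resample_inplane <- function(slice, target_spacing = 1,
                             method = c("bspline", "nearest")) {
  method <- match.arg(method)
  if (!inherits(slice, "image_slice")) slice <- image_slice(slice)
  if (target_spacing <= 0) stop("target_spacing must be > 0")
  if (!all(is.finite(slice$pixels))) stop("non-finite pixels in input")
  sp <- slice$spacing
  if (all(abs(sp - target_spacing) < 1e-12)) return(slice)

  px <- slice$pixels
  resample_axis <- function(mat, spacing_in, n_axis) {
    n_in <- n_axis
    n_out <- max(1L, round(n_in * spacing_in / target_spacing))
    old <- (seq_len(n_in) - 1) * spacing_in
    new <- pmin((seq_len(n_out) - 1) * target_spacing, max(old))
    list(n_out = n_out, old = old, new = new)
  }
  interp_vec <- function(y, old, new) {
    if (length(old) == 1) return(rep(y, length(new)))
    if (method == "nearest") {
      idx <- pmin(pmax(round(new / (old[2] - old[1])) + 1, 1), length(old))
      y[idx]
    } else if (length(old) < 4) {
      # too few samples for a cubic fit: linear
      stats::approx(old, y, xout = new, rule = 2)$y
    } else {
      splinefun(old, y, method = "fmm")(new)
    }
  }
  ax_r <- resample_axis(px, sp[1], nrow(px))
  ax_c <- resample_axis(px, sp[2], ncol(px))
  tmp <- apply(px, 2, interp_vec, old = ax_r$old, new = ax_r$new)
  tmp <- matrix(tmp, nrow = ax_r$n_out)
  out <- t(apply(tmp, 1, interp_vec, old = ax_c$old, new = ax_c$new))
  out <- matrix(out, nrow = ax_r$n_out)
  image_slice(out, c(target_spacing, target_spacing))
}

# Maximal Feret (in-plane) diameter of a mask, in pixels, via the convex
# hull of in-mask pixel centers.
feret_diameter <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) return(-Inf)
  if (nrow(pts) == 1) return(0)
  hull <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[hull, , drop = FALSE]
  max(stats::dist(hp))
}

#' Select the slice of maximal in-plane diameter
#'
#' Scans a stack of slices and returns the one whose mask has the largest
#' maximal Feret diameter; ties are broken by the lowest slice index.
#'
#' @param volume 3-D numeric array (row, col, slice) or list of matrices.
#' @param mask_volume Matching binary array/list.
#' @return List with `slice` (matrix), `mask` (logical matrix), `index`.
#' @export
select_max_diameter_slice <- function(volume, mask_volume) {
  as_list <- function(v) {
    if (is.list(v)) lapply(v, as.matrix)
    else lapply(seq_len(dim(v)[3]), function(k) v[, , k])
  }
  vols <- as_list(volume)
  masks <- lapply(as_list(mask_volume), function(m) m > 0.5)
  if (length(vols) != length(masks)) stop("volume/mask slice counts differ")
  d <- vapply(masks, feret_diameter, numeric(1))
  if (all(!is.finite(d))) stop("mask is empty on every slice")
  idx <- which.max(d)  # which.max takes the first maximum: lowest index
  list(slice = vols[[idx]], mask = masks[[idx]], index = idx)
}

#' Construct a quantized ROI
#'
#' @param levels Integer matrix with values in 1..n_levels inside the
#'   mask, `NA` outside.
#' @param mask Logical matrix (nonempty).
#' @param n_levels Number of gray levels B (>= 2).
#' @param bounds The (min, max) used for normalization.
#' @return A `quantized_roi` object.
#' @export
quantized_roi <- function(levels, mask, n_levels, bounds = c(NA, NA)) {
  if (!any(mask)) stop("mask is empty")
  if (n_levels < 2) stop("n_levels must be >= 2")
  inm <- levels[mask]
  if (any(is.na(inm)) || any(inm < 1 | inm > n_levels))
    stop("in-mask levels must lie in 1..n_levels")
  structure(list(levels = levels, mask = mask,
                 n_levels = as.integer(n_levels),
                 bounds = as.numeric(bounds)),
            class = "quantized_roi")
}

#' Min-max normalize and quantize an ROI
#'
#' In-mask intensities are rescaled to \[0, 1\] using the in-mask minimum
#' and maximum (configurable to whole-slice bounds via `bounds`), then
#' mapped to level `floor(v * B) + 1` with `v = 1` assigned level `B`.
#' A flat region maps everything to level 1.
#'
#' @param slice An [image_slice()] or numeric matrix.
#' @param mask Logical matrix, same shape, nonempty.
#' @param n_levels Number of levels B (default 8).
#' @param bounds Optional explicit (min, max) normalization bounds.
#' @return A [quantized_roi()].
#' @export
normalize_quantize <- function(slice, mask, n_levels = 8, bounds = NULL) {
  px <- if (inherits(slice, "image_slice")) slice$pixels else as.matrix(slice)
  mask <- mask > 0.5
  if (!any(mask)) stop("mask is empty")
  if (n_levels < 2) stop("n_levels must be >= 2")
  x <- px[mask]
  if (is.null(bounds)) bounds <- range(x)
  mn <- bounds[1]; mx <- bounds[2]
  lev <- matrix(NA_integer_, nrow(px), ncol(px))
  if (mx - mn <= 0) {
    lev[mask] <- 1L
  } else {
    v <- pmin(pmax((x - mn) / (mx - mn), 0), 1)
    lev[mask] <- as.integer(pmin(floor(v * n_levels) + 1, n_levels))
  }
  quantized_roi(lev, mask, n_levels, c(mn, mx))
}

#' Write / read one case as NIfTI image+mask plus metadata
#'
#' @param case A `case_record`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_case_nifti <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_path <- file.path(dir, paste0(case$case_id, "_image.nii.gz"))
  msk_path <- file.path(dir, paste0(case$case_id, "_mask.nii.gz"))
  RNifti::writeNifti(
    RNifti::asNifti(case$image, pixdim = case$spacing), img_path)
  RNifti::writeNifti(
    RNifti::asNifti(array(as.numeric(case$mask), dim = dim(case$mask)),
                    pixdim = case$spacing), msk_path)
  invisible(c(image = img_path, mask = msk_path))
}

#' @rdname write_case_nifti
#' @param case_id Case identifier used in the file names.
#' @export
read_case_nifti <- function(dir, case_id) {
  img <- RNifti::readNifti(file.path(dir, paste0(case_id, "_image.nii.gz")))
  msk <- RNifti::readNifti(file.path(dir, paste0(case_id, "_mask.nii.gz")))
  sp <- RNifti::pixdim(img)[1:2]
  list(image = image_slice(as.matrix(img[, ]), sp),
       mask = as.matrix(msk[, ]) > 0.5)
}

#' Write a cohort to disk (NIfTI images/masks + CSV table)
#'
#' @param cohort List of `case_record`s.
#' @param dir Output directory.
#' @param write_images Write per-case NIfTI files (default TRUE).
#' @return Invisibly, the CSV path.
#' @export
write_cohort <- function(cohort, dir, write_images = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (write_images) for (cs in cohort) write_case_nifti(cs, dir)
  tab <- cohort_table(cohort)
  path <- file.path(dir, "cohort.csv")
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding `cohort.csv` and the NIfTI pairs.
#' @return List of `case_record`s.
#' @export
read_cohort <- function(dir) {
  tab <- read.csv(file.path(dir, "cohort.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    nf <- read_case_nifti(dir, row$case_id)
    structure(list(case_id = row$case_id,
                   image = nf$image$pixels, mask = nf$mask,
                   spacing = nf$image$spacing,
                   age = row$age, gender = row$gender,
                   tumor_location = row$tumor_location,
                   histological_grade = row$histological_grade,
                   short_axis = row$short_axis, long_axis = row$long_axis,
                   label = as.integer(row$label)),
              class = "case_record")
  })
}

#' Dump a quantized ROI to CSV (debugging aid)
#'
#' Out-of-mask cells are written as `NA`.
#'
#' @param roi A [quantized_roi()].
#' @param path Output path.
#' @export
write_quantized_csv <- function(roi, path) {
  write.table(roi$levels, path, sep = ",", row.names = FALSE,
              col.names = FALSE, na = "NA")
  invisible(path)
}
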