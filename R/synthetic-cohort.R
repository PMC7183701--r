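# Synthetic lymph-node cohort generator.
#
# Each case is a single 2-D CT-like slice holding one elliptical lymph node.
# Node size follows a truncated-normal law whose *truncated* mean/SD match
# the published per-class long-axis statistics; interior texture is a
# stationary Gaussian random field (squared-exponential correlation) whose
# amplitude differs between classes, so that size and texture - and nothing
# else - carry the class signal.

#' Per-class lesion generation parameters
#'
#' Bundles the geometric and texture parameters used to simulate one class
#' of lymph nodes. The long-axis diameter is drawn from a normal
#' distribution truncated below at 4 mm whose parent parameters are solved
#' internally so that the truncated distribution has exactly
#' `long_axis_mean` / `long_axis_sd`.
#'
#' @param class_label `"normal"` or `"metastatic"`.
#' @param long_axis_mean Target mean long-axis diameter (mm).
#' @param long_axis_sd Target SD of the long-axis diameter (mm).
#' @param axis_ratio_range Length-2 numeric in (0, 1]: the short/long axis
#'   ratio is drawn uniformly from this interval.
#' @param texture_contrast_scale Dimensionless amplitude multiplier for the
#'   interior texture field (0 disables texture).
#' @param texture_correlation_length Correlation length of the texture
#'   field in mm (> 0).
#' @param noise_sd SD of additive white pixel noise (intensity units).
#' @return An object of class `lesion_params`.
#' @export
lesion_params <- function(class_label = c("normal", "metastatic"),
                          long_axis_mean,
                          long_axis_sd,
                          axis_ratio_range = c(0.55, 0.9),
                          texture_contrast_scale = 0.5,
                          texture_correlation_length = 2.5,
                          noise_sd = 2) {
  class_label <- match.arg(class_label)
  if (!is.numeric(long_axis_mean) || long_axis_mean <= 0)
    stop("long_axis_mean must be > 0")
  if (!is.numeric(long_axis_sd) || long_axis_sd < 0)
    stop("long_axis_sd must be >= 0")
  if (length(axis_ratio_range) != 2 ||
      any(axis_ratio_range <= 0) || any(axis_ratio_range > 1) ||
      axis_ratio_range[1] > axis_ratio_range[2])
    stop("axis_ratio_range must be an increasing pair within (0, 1]")
  if (texture_contrast_scale < 0) stop("texture_contrast_scale must be >= 0")
  if (texture_correlation_length <= 0)
    stop("texture_correlation_length must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(class_label = class_label,
                 long_axis_mean = long_axis_mean,
                 long_axis_sd = long_axis_sd,
                 axis_ratio_range = axis_ratio_range,
                 texture_contrast_scale = texture_contrast_scale,
                 texture_correlation_length = texture_correlation_length,
                 noise_sd = noise_sd),
            class = "lesion_params")
}

#' Default per-class lesion parameters
#'
#' Normal nodes: long axis 12.12 +/- 5.74 mm; metastatic nodes:
#' 17.37 +/- 8.48 mm. Metastatic interiors are more heterogeneous
#' (larger texture contrast), reflecting the internal-heterogeneity
#' rationale behind CT texture analysis of nodal metastasis.
#'
#' @param class_label `"normal"` or `"metastatic"`.
#' @return A [lesion_params()] object.
#' @export
default_lesion_params <- function(class_label = c("normal", "metastatic")) {
  class_label <- match.arg(class_label)
  if (class_label == "normal") {
    lesion_params("normal", long_axis_mean = 12.12, long_axis_sd = 5.74,
                  texture_contrast_scale = 0.4)
  } else {
    lesion_params("metastatic", long_axis_mean = 17.37, long_axis_sd = 8.48,
                  texture_contrast_scale = 1.0)
  }
}

# Base interior intensity and the texture amplitude per unit contrast
# scale, in arbitrary intensity units (the published study reports no
# interior intensity statistics; features are intensity-affine-invariant
# so the absolute values are immaterial).
.base_level <- 100
.background_level <- 60
.texture_unit_sd <- 15
.long_axis_lower <- 4   # mm truncation bound for the size law
.min_short_axis <- 4    # mm floor so every mask spans >= 4 px at 1 mm
                        # in any orientation (wavelet/LBP preconditions)

# Stationary unit-variance Gaussian random field with squared-exponential
# correlation exp(-d^2 / (2 ell^2)), by valid convolution of white noise
# with a separable Gaussian kernel.
gaussian_random_field <- function(nr, nc, corr_length_px) {
  s <- corr_length_px / sqrt(2)
  h <- max(1L, ceiling(3 * s))
  k <- dnorm(seq(-h, h), sd = s)
  w <- matrix(rnorm((nr + 2 * h) * (nc + 2 * h)), nr + 2 * h, nc + 2 * h)
  # banded convolution matrices (valid part only)
  band <- function(n) {
    b <- matrix(0, n, n + 2 * h)
    for (i in seq_len(n)) b[i, i:(i + 2 * h)] <- k
    b
  }
  f <- band(nr) %*% w %*% t(band(nc))
  f / sum(k^2)  # valid conv of unit white noise has SD = sum(k^2)
}

#' Generate one synthetic lymph-node case
#'
#' Draws an elliptical mask (random orientation, long axis from the
#' truncated-normal size law, short axis from the axis-ratio range, floored
#' at 4 mm so the node spans at least 4 pixels in any orientation), fills
#' the interior with
#' a smooth base level plus a correlated Gaussian texture field plus white
#' noise, and attaches demographic covariates drawn independently of the
#' texture given the class label.
#'
#' @param params A [lesion_params()] object.
#' @param seed Integer seed; the same (params, seed) pair reproduces the
#'   case bit-for-bit.
#' @param pixel_spacing Pixel spacing in mm (default 1).
#' @param case_id Optional case identifier string.
#' @return A `case_record`: list with `case_id`, `image`, `mask`,
#'   `spacing`, `age`, `gender`, `tumor_location`, `histological_grade`,
#'   `short_axis`, `long_axis`, `label`.
#' @export
generate_lesion <- function(params, seed, pixel_spacing = 1,
                            case_id = "case_0001") {
  if (!inherits(params, "lesion_params")) stop("params must be lesion_params")
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be > 0")
  with_seed(seed, {
    par_fit <- truncnorm_match(params$long_axis_mean,
                               max(params$long_axis_sd, 1e-6),
                               .long_axis_lower)
    long_axis <- rtruncnorm_lower(1, par_fit$mu, par_fit$sigma,
                                  .long_axis_lower)
    ratio <- runif(1, params$axis_ratio_range[1], params$axis_ratio_range[2])
    short_axis <- max(ratio * long_axis, .min_short_axis)
    if (short_axis > long_axis) short_axis <- long_axis
    theta <- runif(1, 0, pi)

    margin <- 4
    n <- ceiling(long_axis / pixel_spacing) + 2 * margin + 1
    if (n %% 2 == 0) n <- n + 1  # odd grid: ellipse center on a pixel
    ctr <- (n + 1) / 2
    xy <- expand.grid(row = seq_len(n), col = seq_len(n))
    x <- (xy$col - ctr) * pixel_spacing
    y <- (xy$row - ctr) * pixel_spacing
    xr <- x * cos(theta) + y * sin(theta)
    yr <- -x * sin(theta) + y * cos(theta)
    a <- long_axis / 2
    b <- short_axis / 2
    mask <- matrix((xr / a)^2 + (yr / b)^2 <= 1, n, n)
    if (!any(mask)) stop("degenerate lesion: empty mask")

    image <- matrix(.background_level, n, n)
    if (params$texture_contrast_scale > 0) {
      fld <- gaussian_random_field(
        n, n, params$texture_correlation_length / pixel_spacing)
      tex <- .base_level +
        params$texture_contrast_scale * .texture_unit_sd * fld
    } else {
      tex <- matrix(.base_level, n, n)
    }
    image[mask] <- tex[mask]
    if (params$noise_sd > 0)
      image[mask] <- image[mask] + rnorm(sum(mask), 0, params$noise_sd)

    age <- round(min(max(rnorm(1, 62, 13), 30), 92))
    gender <- sample(c("M", "F"), 1)
    location <- sample(c("left", "right"), 1)
    grade <- sample(c("well", "poor"), 1, prob = c(0.65, 0.35))

    structure(list(case_id = case_id,
                   image = image,
                   mask = mask,
                   spacing = c(pixel_spacing, pixel_spacing),
                   age = age,
                   gender = gender,
                   tumor_location = location,
                   histological_grade = grade,
                   short_axis = short_axis,
                   long_axis = long_axis,
                   label = if (params$class_label == "metastatic") 1L else 0L),
              class = "case_record")
  })
}

#' Cohort simulation configuration
#'
#' @param n_normal,n_metastatic Non-negative class counts.
#' @param seed Integer master seed.
#' @param pixel_spacing Pixel spacing in mm.
#' @param normal_params,metastatic_params Per-class [lesion_params()].
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(n_normal, n_metastatic, seed = 1,
                          pixel_spacing = 1,
                          normal_params = default_lesion_params("normal"),
                          metastatic_params = default_lesion_params("metastatic")) {
  if (n_normal < 0 || n_metastatic < 0) stop("class counts must be >= 0")
  if (pixel_spacing <= 0) stop("pixel_spacing must be > 0")
  structure(list(n_normal = as.integer(n_normal),
                 n_metastatic = as.integer(n_metastatic),
                 seed = as.integer(seed),
                 pixel_spacing = pixel_spacing,
                 normal_params = normal_params,
                 metastatic_params = metastatic_params),
            class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Produces `n_normal + n_metastatic` case records, each generated from a
#' per-case sub-seed derived deterministically from the master seed, so the
#' whole cohort is reproducible and cases are independent.
#'
#' @param config A [cohort_config()] object.
#' @return List of `case_record` objects (normal cases first).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be cohort_config")
  n_total <- config$n_normal + config$n_metastatic
  if (n_total == 0) return(list())
  seeds <- derive_seeds(config$seed, n_total)
  labels <- c(rep("normal", config$n_normal),
              rep("metastatic", config$n_metastatic))
  lapply(seq_len(n_total), function(i) {
    prm <- if (labels[i] == "normal") config$normal_params
           else config$metastatic_params
    generate_lesion(prm, seed = seeds[i],
                    pixel_spacing = config$pixel_spacing,
                    case_id = sprintf("case_%04d", i))
  })
}

#' Cohort demographics/size table
#'
#' @param cohort List of `case_record`s.
#' @return A data frame with one row per case (case_id, age, gender,
#'   tumor_location, histological_grade, short_axis, long_axis, label).
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(cs) {
    data.frame(case_id = cs$case_id, age = cs$age, gender = cs$gender,
               tumor_location = cs$tumor_location,
               histological_grade = cs$histological_grade,
               short_axis = cs$short_axis, long_axis = cs$long_axis,
               label = cs$label, stringsAsFactors = FALSE)
  }))
}

#' Hand-checkable fixture matrices
#'
#' Tiny quantized ROIs with enumerable co-occurrence / run-length
#' structure, used throughout the test-suite oracles:
#' \describe{
#'   \item{constant_4x4}{4x4 single gray level, full mask.}
#'   \item{ramp_4x4}{values 1..16 row-wise, quantized to 8 levels.}
#'   \item{checker_4x4}{4x4 checkerboard of levels 1 and 2.}
#'   \item{two_level_2x2}{values \code{rbind(c(0,0), c(1,1))}, 2 levels.}
#'   \item{line_mask}{64x64 grid, single middle row masked, constant value.}
#'   \item{disk_mask_r10}{binary disk of radius 10 px on a 25x25 grid.}
#' }
#'
#' @param name Fixture name.
#' @return A `quantized_roi` object; the raw (pre-quantization) values are
#'   attached as attribute `"values"`.
#' @export
fixture_matrix <- function(name) {
  build <- switch(
    name,
    constant_4x4 = {
      v <- matrix(5, 4, 4)
      list(values = v, mask = matrix(TRUE, 4, 4), n_levels = 8L)
    },
    ramp_4x4 = {
      v <- matrix(1:16, 4, 4, byrow = TRUE)
      list(values = v, mask = matrix(TRUE, 4, 4), n_levels = 8L)
    },
    checker_4x4 = {
      v <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
      list(values = v, mask = matrix(TRUE, 4, 4), n_levels = 2L)
    },
    two_level_2x2 = {
      v <- rbind(c(0, 0), c(1, 1))
      list(values = v, mask = matrix(TRUE, 2, 2), n_levels = 2L)
    },
    line_mask = {
      v <- matrix(1, 64, 64)
      m <- matrix(FALSE, 64, 64)
      m[32, ] <- TRUE
      list(values = v, mask = m, n_levels = 8L)
    },
    disk_mask_r10 = {
      ctr <- 13
      m <- outer(1:25, 1:25, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= 100)
      v <- matrix(1, 25, 25)
      list(values = v, mask = m, n_levels = 8L)
    },
    stop("unknown fixture name: ", name)
  )
  roi <- normalize_quantize(build$values, build$mask, n_levels = build$n_levels)
  attr(roi, "values") <- build$values
  roi
}
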