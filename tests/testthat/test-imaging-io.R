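# Resampling, slice selection, normalization/quantization, NIfTI IO.

test_that("resampling preserves constants and passes identity through", {
  cst <- image_slice(matrix(7, 20, 20), spacing = 0.7)
  out <- resample_inplane(cst, 1)
  expect_equal(out$spacing, c(1, 1))
  expect_true(all(abs(out$pixels - 7) < 1e-9))

  idn <- image_slice(matrix(rnorm(100), 10, 10), spacing = 1)
  expect_identical(resample_inplane(idn, 1), idn)
})

test_that("cubic resampling reproduces a linear ramp away from borders", {
  n <- 30
  ramp <- image_slice(outer(1:n, 1:n, function(i, j) 2 * i + 3 * j),
                      spacing = 0.7)
  out <- resample_inplane(ramp, 1)
  # direct evaluation of the same plane at the output pixel coordinates
  xo <- (seq_len(nrow(out$pixels)) - 1) * 1 / 0.7 + 1
  yo <- (seq_len(ncol(out$pixels)) - 1) * 1 / 0.7 + 1
  expected <- outer(xo, yo, function(i, j) 2 * i + 3 * j)
  core_r <- 3:(nrow(out$pixels) - 3)
  core_c <- 3:(ncol(out$pixels) - 3)
  rel <- abs(out$pixels - expected)[core_r, core_c] /
    abs(expected[core_r, core_c])
  expect_lt(max(rel), 1e-6)
})

test_that("resampling round-trips a smooth image within 1e-3 relative RMS", {
  n <- 40
  smooth <- outer(1:n, 1:n, function(i, j)
    100 + 20 * sin(i / 8) * cos(j / 9))
  s1 <- image_slice(smooth, spacing = 1)
  down <- resample_inplane(s1, 0.7)
  back <- resample_inplane(down, 1)
  expect_equal(dim(back$pixels), dim(smooth))
  core <- 4:(n - 4)
  rel_rms <- sqrt(mean((back$pixels - smooth)[core, core]^2)) /
    sqrt(mean(smooth[core, core]^2))
  expect_lt(rel_rms, 1e-3)
})

test_that("max-diameter slice selection picks the largest mask", {
  m_small <- outer(1:15, 1:15, function(i, j) (i - 8)^2 + (j - 8)^2 <= 9)
  m_large <- outer(1:15, 1:15, function(i, j) (i - 8)^2 + (j - 8)^2 <= 25)
  empty <- matrix(FALSE, 15, 15)
  vol <- array(rnorm(15 * 15 * 3), dim = c(15, 15, 3))

  one <- select_max_diameter_slice(vol, array(c(empty, m_small, empty),
                                              dim = c(15, 15, 3)))
  expect_equal(one$index, 2)

  two <- select_max_diameter_slice(vol, array(c(m_small, empty, m_large),
                                              dim = c(15, 15, 3)))
  expect_equal(two$index, 3)

  tie <- select_max_diameter_slice(vol, array(c(m_small, m_small, empty),
                                              dim = c(15, 15, 3)))
  expect_equal(tie$index, 1)

  expect_error(select_max_diameter_slice(vol, array(FALSE, c(15, 15, 3))),
               "empty")
})

test_that("quantization follows the binning rule", {
  v <- matrix(seq(10, 80, by = 10), 2, 4)
  roi <- normalize_quantize(v, matrix(TRUE, 2, 4), 8)
  expect_equal(sort(roi$levels[roi$mask]), 1:8)

  flat <- normalize_quantize(matrix(5, 3, 3), matrix(TRUE, 3, 3), 8)
  expect_true(all(flat$levels == 1))

  v2 <- matrix(c(0, 0.49, 0.5, 1), 1, 4)
  roi2 <- normalize_quantize(v2, matrix(TRUE, 1, 4), 2)
  expect_equal(as.integer(roi2$levels), c(1L, 1L, 2L, 2L))

  expect_error(normalize_quantize(v, matrix(FALSE, 2, 4), 8), "empty")
  expect_error(normalize_quantize(v, matrix(TRUE, 2, 4), 1), "n_levels")
})

test_that("quantization is monotone and affine-invariant", {
  set.seed(42)
  for (rep in 1:20) {
    v <- matrix(rnorm(49), 7, 7)
    mask <- matrix(TRUE, 7, 7)
    roi <- normalize_quantize(v, mask, 8)
    ord <- order(v[mask])
    expect_true(all(diff(roi$levels[mask][ord]) >= 0))
    a <- runif(1, 0.1, 5); b <- rnorm(1, 0, 10)
    roi2 <- normalize_quantize(a * v + b, mask, 8)
    expect_identical(roi$levels, roi2$levels)
  }
})

test_that("normalization bounds come from in-mask pixels only", {
  v <- matrix(0, 5, 5)
  v[2:4, 2:4] <- matrix(1:9, 3, 3)
  v[1, 1] <- 1000  # extreme value outside the mask
  mask <- matrix(FALSE, 5, 5); mask[2:4, 2:4] <- TRUE
  roi <- normalize_quantize(v, mask, 8)
  expect_equal(roi$bounds, c(1, 9))
  expect_equal(max(roi$levels[mask]), 8L)
})

test_that("cases round-trip through NIfTI files", {
  cs <- generate_lesion(default_lesion_params("normal"), seed = 4)
  dir <- tempfile("niftitest")
  write_case_nifti(cs, dir)
  back <- read_case_nifti(dir, cs$case_id)
  expect_equal(back$image$pixels, cs$image, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unname(back$image$spacing), unname(cs$spacing))
  expect_identical(unname(back$mask), unname(cs$mask))
  unlink(dir, recursive = TRUE)
})

test_that("cohorts round-trip through the cohort writer", {
  co <- generate_cohort(cohort_config(3, 2, seed = 9))
  dir <- tempfile("cohorttest")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_length(back, 5)
  expect_equal(vapply(back, `[[`, integer(1), "label"),
               vapply(co, `[[`, integer(1), "label"))
  expect_equal(back[[4]]$image, co[[4]]$image, tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
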