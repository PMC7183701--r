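# Synthetic lymph-node generator: determinism, size law, class signal.

test_that("lesion generation is reproducible and validates parameters", {
  p <- default_lesion_params("normal")
  a <- generate_lesion(p, seed = 7)
  b <- generate_lesion(p, seed = 7)
  expect_identical(a, b)
  d <- generate_lesion(p, seed = 8)
  expect_false(identical(a$image, d$image))
  expect_error(generate_lesion(p, seed = 1, pixel_spacing = 0),
               "pixel_spacing")
  expect_error(lesion_params("normal", long_axis_mean = -1,
                             long_axis_sd = 1), "long_axis_mean")
  expect_error(lesion_params("normal", 12, 5, axis_ratio_range = c(0, 2)),
               "axis_ratio_range")
})

test_that("zero texture and zero noise give a constant interior", {
  p <- lesion_params("normal", 12.12, 5.74,
                     texture_contrast_scale = 0, noise_sd = 0)
  cs <- generate_lesion(p, seed = 3)
  expect_equal(var(cs$image[cs$mask]), 0)
})

test_that("mask geometry agrees with the drawn axes to about a pixel", {
  for (s in 1:10) {
    cs <- generate_lesion(default_lesion_params("metastatic"), seed = s)
    feret <- max(dist(which(cs$mask, arr.ind = TRUE)))
    # pixel-center Feret of a digitized ellipse sits just inside the
    # continuous long axis
    expect_lte(feret, cs$long_axis + 1)
    expect_gte(feret, cs$long_axis - 2.5)
    expect_gte(cs$long_axis, cs$short_axis)
    expect_gte(cs$short_axis, 4)
  }
})

test_that("long-axis distribution recovers the configured moments", {
  draws <- function(params, n, seed0) {
    vapply(seq_len(n), function(i)
      generate_lesion(params, seed = seed0 + i)$long_axis, numeric(1))
  }
  ln <- draws(default_lesion_params("normal"), 500, 10000)
  lm <- draws(default_lesion_params("metastatic"), 500, 20000)
  expect_lt(abs(mean(ln) - 12.12), 0.5)
  expect_lt(abs(mean(ln) - 12.12) / 12.12, 0.10)
  expect_lt(abs(sd(ln) - 5.74) / 5.74, 0.10)
  expect_lt(abs(mean(lm) - 17.37) / 17.37, 0.10)
  expect_lt(abs(sd(lm) - 8.48) / 8.48, 0.10)
  expect_gte(min(c(ln, lm)), 4)
})

test_that("interior heterogeneity separates the classes", {
  var_of <- function(params, n, seed0) {
    vapply(seq_len(n), function(i) {
      cs <- generate_lesion(params, seed = seed0 + i)
      var(cs$image[cs$mask])
    }, numeric(1))
  }
  v0 <- var_of(default_lesion_params("normal"), 200, 500)
  v1 <- var_of(default_lesion_params("metastatic"), 200, 900)
  p <- wilcox.test(v0, v1)$p.value
  expect_lt(p, 0.01)
})

test_that("cohort generation respects counts, labels and the seed", {
  co <- generate_cohort(cohort_config(157, 155, seed = 1))
  expect_length(co, 312)
  labs <- vapply(co, `[[`, integer(1), "label")
  expect_equal(sum(labs == 0), 157)
  expect_equal(sum(labs == 1), 155)
  co2 <- generate_cohort(cohort_config(157, 155, seed = 1))
  expect_identical(co, co2)

  expect_length(generate_cohort(cohort_config(0, 0, seed = 5)), 0)

  bal <- generate_cohort(cohort_config(39, 39, seed = 2))
  expect_length(bal, 78)
  expect_equal(sum(vapply(bal, `[[`, integer(1), "label")), 39)
})

test_that("fixture registry returns the documented matrices", {
  cst <- fixture_matrix("constant_4x4")
  expect_true(all(cst$levels == 1))
  expect_equal(dim(cst$levels), c(4, 4))

  two <- fixture_matrix("two_level_2x2")
  expect_equal(unname(two$levels), rbind(c(1L, 1L), c(2L, 2L)))
  expect_equal(two$n_levels, 2L)

  disk <- fixture_matrix("disk_mask_r10")
  expect_equal(dim(disk$mask), c(25, 25))
  expect_equal(sum(disk$mask), 317)  # digital disk of radius 10

  expect_error(fixture_matrix("no_such_fixture"), "unknown fixture")
})
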