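test_that("parameter validation rejects malformed settings", {
  expect_error(phantom_params(patch_size = 32), "patch_size")
  expect_error(phantom_params(n_tubules_range = c(3, 1)), "min <= max")
  expect_error(phantom_params(incomplete_fraction = 1.2), "incomplete_fraction")
  expect_error(phantom_params(lumen_radius_range = c(0, 5)), "positive")
})

test_that("an empty scene yields an all-zero mask and background image", {
  p <- generate_patch(phantom_params(patch_size = 64,
                                     n_tubules_range = c(0L, 0L),
                                     distractor_count_range = c(0L, 0L),
                                     empty_fraction = 0, noise_sd = 0, seed = 5))
  expect_equal(sum(p$mask), 0)
  expect_equal(p$tubule_count, 0)
  expect_equal(dim(p$image), c(64L, 64L, 3L))
  # flat background fill
  expect_equal(length(unique(as.vector(p$image[, , 1]))), 1L)
})

test_that("identical parameters give bit-identical patches", {
  pp <- small_params(seed = 7L)
  expect_identical(generate_patch(pp), generate_patch(pp))
})

test_that("spaced complete tubules appear as that many connected components", {
  pp <- phantom_params(patch_size = 128, n_tubules_range = c(3L, 3L),
                       lumen_radius_range = c(6, 9),
                       ring_thickness_range = c(2, 3),
                       incomplete_fraction = 0, empty_fraction = 0,
                       distractor_count_range = c(0L, 0L),
                       placement = "spaced", seed = 11L)
  p <- generate_patch(pp)
  expect_equal(p$tubule_count, 3)
  # flood-fill component count from an independent labelling routine
  expect_equal(max(EBImage::bwlabel(p$mask)), 3)
})

test_that("mask support equals the union of instance footprints", {
  p <- generate_patch(small_params(seed = 21L))
  h <- nrow(p$mask); w <- ncol(p$mask)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      inside <- any(vapply(p$instances, function(inst) {
        oracle_in_ellipse(i, j, inst)
      }, logical(1)))
      if (inside != (p$mask[i, j] == 1)) {
        fail(sprintf("mask/oracle disagree at (%d, %d)", i, j))
      }
    }
  }
  succeed()
})

test_that("distractor pixels never enter the mask", {
  pp <- phantom_params(patch_size = 64, n_tubules_range = c(0L, 0L),
                       lumen_radius_range = c(5, 9),
                       ring_thickness_range = c(2, 4),
                       distractor_count_range = c(3L, 3L),
                       empty_fraction = 0, seed = 9)
  p <- generate_patch(pp)
  expect_gt(length(p$distractors), 0)
  expect_equal(sum(p$mask), 0)
  # distractors are visible in the image even though absent from the mask
  bg <- pp$stain_palette$background[1] / 255
  expect_gt(sum(abs(p$image[, , 1] - bg) > 0.1), 0)
})

test_that("fully incomplete tubules touch the patch border", {
  for (s in 1:5) {
    p <- generate_patch(small_params(seed = 100L + s,
                                     incomplete_fraction = 1))
    border <- c(p$mask[1, ], p$mask[nrow(p$mask), ],
                p$mask[, 1], p$mask[, ncol(p$mask)])
    expect_gt(sum(border), 0)
  }
})

test_that("dataset generation honours lengths, determinism and disjoint splits", {
  pp <- small_params()
  ds0 <- generate_dataset(pp, 0, 0, seed = 1)
  expect_length(ds0$train, 0)
  expect_length(ds0$val, 0)
  ds <- generate_dataset(pp, 41, 10, seed = 2)
  expect_length(ds$train, 41)
  expect_length(ds$val, 10)
  ds2 <- generate_dataset(pp, 41, 10, seed = 2)
  expect_identical(ds, ds2)
  expect_false(identical(ds$train[[1]], ds$val[[1]]))
})

test_that("large images satisfy the shape contract and determinism", {
  pp <- small_params(seed = 13L)
  expect_error(generate_large_image(pp, 32, 128), ">= patch_size")
  big <- generate_large_image(pp, 150, 130)
  expect_equal(dim(big$image), c(150L, 130L, 3L))
  expect_equal(dim(big$mask), c(150L, 130L))
  expect_identical(big, generate_large_image(pp, 150, 130))
  empty <- phantom_params(patch_size = 64, n_tubules_range = c(0L, 0L),
                          distractor_count_range = c(0L, 0L), seed = 1)
  expect_equal(sum(generate_large_image(empty, 100, 100)$mask), 0)
})
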