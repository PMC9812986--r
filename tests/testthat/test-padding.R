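test_that("reflection padding doubles the canvas and lays out the four flips", {
  p <- generate_patch(small_params(seed = 2L))
  rp <- reflection_pad(p)
  s <- 64L
  expect_equal(dim(rp$image), c(2L * s, 2L * s, 3L))
  expect_equal(rp$core_box, c(0L, 0L, s, s))
  orig <- rp$image[1:s, 1:s, , drop = FALSE]
  expect_identical(orig, p$image)
  # top-right: each row is the original row reversed column-wise
  expect_identical(rp$image[1:s, (2 * s):(s + 1), ], p$image)
  # bottom-left: top-bottom flip; bottom-right: both axes
  expect_identical(rp$image[(2 * s):(s + 1), 1:s, ], p$image)
  expect_identical(rp$image[(2 * s):(s + 1), (2 * s):(s + 1), ], p$image)
  # mask transformed identically to the image
  expect_identical(rp$mask[1:s, (2 * s):(s + 1)], p$mask)
})

test_that("a 1x1 patch reflects to a constant 2x2 canvas", {
  v <- array(0.3, dim = c(1, 1, 3))
  rp <- reflection_pad(v)
  expect_equal(dim(rp$image), c(2L, 2L, 3L))
  expect_true(all(rp$image == 0.3))
})

test_that("reflection canvas is seam-continuous at every internal seam", {
  p <- generate_patch(small_params(seed = 3L))
  rp <- reflection_pad(p)
  s <- 64L
  expect_identical(rp$image[, s, ], rp$image[, s + 1, ])
  expect_identical(rp$image[s, , ], rp$image[s + 1, , ])
})

test_that("mirror padding produces side + 2*margin with reflected bands", {
  p <- generate_patch(small_params(seed = 4L))
  mp <- mirror_pad(p, margin = 10L)
  expect_equal(dim(mp$image), c(84L, 84L, 3L))
  expect_equal(mp$core_box, c(10L, 10L, 74L, 74L))
  # north band: rows above the core mirror rows 2..margin+1 (no edge repeat)
  for (k in 1:10) {
    expect_identical(mp$image[10 - k + 1, 11:74, ], p$image[k + 1, , ])
  }
  # constant patch stays constant
  cp <- array(0.7, dim = c(32, 32, 3))
  expect_true(all(mirror_pad(cp, 8L)$image == 0.7))
})

test_that("mirror padding with margin 0 is the identity", {
  p <- generate_patch(small_params(seed = 5L))
  mp <- mirror_pad(p, 0L)
  expect_identical(mp$image, p$image)
  expect_identical(mp$mask, p$mask)
})

test_that("margin >= side is rejected and non-square patches error", {
  p <- generate_patch(small_params())
  expect_error(mirror_pad(p, 64L), "margin")
  rect <- array(0, dim = c(32, 48, 3))
  expect_error(reflection_pad(rect), "square")
  expect_error(mirror_pad(rect, 4L), "square")
})

test_that("crop_core inverts both padding modes bit-exactly", {
  p <- generate_patch(small_params(seed = 6L))
  expect_identical(crop_core(reflection_pad(p))$image, p$image)
  expect_identical(crop_core(reflection_pad(p))$mask, p$mask)
  for (m in c(1L, 17L, 63L)) {
    cc <- crop_core(mirror_pad(p, m))
    expect_identical(cc$image, p$image)
    expect_identical(cc$mask, p$mask)
  }
})

test_that("mask padding commutes with image padding", {
  p <- generate_patch(small_params(seed = 8L))
  mask_only <- p
  mask_only$image <- array(rep(p$mask, 3), dim = c(dim(p$mask), 3L))
  rp <- reflection_pad(p)
  rp_m <- reflection_pad(mask_only)
  expect_identical(rp$mask, rp_m$image[, , 1])
  mp <- mirror_pad(p, 12L)
  mp_m <- mirror_pad(mask_only, 12L)
  expect_identical(mp$mask, mp_m$image[, , 1])
})

test_that("resize uses bilinear for images and nearest for masks", {
  img <- array(runif(48 * 48 * 3), dim = c(48, 48, 3))
  small <- resize_image(img, 16L)
  expect_equal(dim(small), c(16L, 16L, 3L))
  expect_true(all(small >= min(img) & small <= max(img)))
  mask <- matrix(rbinom(48^2, 1, 0.3), 48, 48)
  sm <- resize_image(mask, 20L, labels = TRUE)
  expect_true(all(sm %in% c(0, 1)))
  # identity resize of a mask is bit-exact
  expect_identical(resize_image(mask, 48L, labels = TRUE), mask)
  # constants are preserved at any target
  ones <- matrix(1, 30, 30)
  expect_true(all(resize_image(ones, 47L, labels = TRUE) == 1))
  expect_true(all(abs(resize_image(ones, 47L) - 1) < 1e-12))
})
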