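test_that("25% overlap on a 900 core plans 1350 tiles", {
  plan <- plan_tiles(1800, 1800, core = 900, overlap_fraction = 0.25)
  expect_equal(plan$tile, 1350L)
  expect_equal(plan$band, 225L)
  expect_equal(nrow(plan$origins), 4L)
  expect_equal(unname(plan$origins),
               matrix(c(0L, 0L, 0L, 900L, 900L, 0L, 900L, 900L),
                      ncol = 2, byrow = TRUE))
})

test_that("zero overlap degenerates to abutting cores", {
  plan <- plan_tiles(128, 128, core = 64, overlap_fraction = 0)
  expect_equal(plan$tile, 64L)
  expect_equal(unname(plan$border_pad), c(0L, 0L, 0L, 0L))
  par <- matrix(runif(128^2), 128, 128)
  tiles <- extract_tiles(par, plan)
  rebuilt <- matrix(0, 128, 128)
  for (k in seq_len(nrow(plan$origins))) {
    o <- plan$origins[k, ]
    rebuilt[o[["row"]] + 1:64, o[["col"]] + 1:64] <- tiles[[k]]$image[, , 1]
  }
  expect_identical(rebuilt, par)
})

test_that("invalid tiling parameters are rejected", {
  expect_error(plan_tiles(100, 100, core = 90, overlap_fraction = 0.13),
               "integer number of pixels")
  expect_error(plan_tiles(100, 100, core = 90, overlap_fraction = 0.7),
               "overlap_fraction")
  expect_error(plan_tiles(0, 100), "positive")
})

test_that("core boxes partition the parent exactly", {
  plan <- plan_tiles(150, 130, core = 64, overlap_fraction = 0.25)
  cover <- matrix(0L, 150, 130)
  for (k in seq_len(nrow(plan$origins))) {
    o <- plan$origins[k, ]
    rows <- (o[["row"]] + 1L):min(o[["row"]] + plan$core, 150L)
    cols <- (o[["col"]] + 1L):min(o[["col"]] + plan$core, 130L)
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  expect_true(all(cover == 1L))
})

test_that("interior tile content equals the matching parent window", {
  par <- matrix(runif(256 * 256), 256, 256)
  plan <- plan_tiles(256, 256, core = 64, overlap_fraction = 0.25)
  # second-row, second-column tile lies fully inside the parent
  k <- which(plan$origins[, "row"] == 64 & plan$origins[, "col"] == 64)
  t <- extract_tiles(par, plan)[[k]]
  # tile spans parent rows/cols (origin - band + 1) .. (+ tile)
  win <- par[(64 - 16 + 1):(64 - 16 + 96), (64 - 16 + 1):(64 - 16 + 96)]
  expect_identical(t$image[, , 1], win)
})

test_that("constant parents yield constant tiles and stitches", {
  par <- matrix(0.42, 100, 80)
  plan <- plan_tiles(100, 80, core = 64, overlap_fraction = 0.25)
  tiles <- extract_tiles(par, plan)
  expect_true(all(vapply(tiles, function(t) all(t$image == 0.42), logical(1))))
  maps <- lapply(tiles, function(t) t$image[, , 1])
  expect_true(all(stitch(maps, plan, "core_crop") == 0.42))
  expect_true(all(abs(stitch(maps, plan, "mean") - 0.42) < 1e-12))
})

test_that("a single-tile plan returns that tile's core", {
  par <- matrix(runif(64^2), 64, 64)
  plan <- plan_tiles(64, 64, core = 64, overlap_fraction = 0.25)
  expect_equal(nrow(plan$origins), 1L)
  tiles <- extract_tiles(par, plan)
  expect_identical(stitch(list(tiles[[1]]$image[, , 1]), plan, "core_crop"), par)
})

test_that("mean blending averages overlapping contributions per pixel", {
  plan <- plan_tiles(128, 64, core = 64, overlap_fraction = 0.25)
  expect_equal(nrow(plan$origins), 2L)
  maps <- list(matrix(0.2, 96, 96), matrix(0.4, 96, 96))
  out <- stitch(maps, plan, "mean")
  # rows covered by both tiles get the average; single-covered keep their own
  expect_true(all(abs(out[1:48, ] - 0.2) < 1e-12))
  expect_true(all(abs(out[49:80, ] - 0.3) < 1e-12))
  expect_true(all(abs(out[81:128, ] - 0.4) < 1e-12))
})

test_that("stitch recovers the parent under core_crop for any overlap", {
  set.seed(5)
  for (ov in c(0, 0.125, 0.25, 0.5)) {
    par <- matrix(runif(150 * 90), 150, 90)
    plan <- plan_tiles(150, 90, core = 64, overlap_fraction = ov)
    maps <- lapply(extract_tiles(par, plan), function(t) t$image[, , 1])
    expect_identical(stitch(maps, plan, "core_crop"), par)
  }
})

test_that("stitch validates tile count and sizes", {
  plan <- plan_tiles(100, 100, core = 64, overlap_fraction = 0.25)
  maps <- lapply(seq_len(nrow(plan$origins)), function(i) matrix(0.5, 96, 96))
  expect_error(stitch(maps[-1], plan), "expects")
  maps[[1]] <- matrix(0.5, 64, 64)
  expect_error(stitch(maps, plan), "tile x tile")
})
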