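test_that("train_config validates its invariants", {
  expect_error(train_config(lr = 0), "lr")
  expect_error(train_config(lr_factor = 0), "lr_factor")
  expect_error(train_config(patience = 60, epochs = 50), "patience")
  expect_error(train_config(batch_size = 0), "batch_size")
  expect_error(train_config(augmentations = "zoom_blur"), "unknown augmentation")
})

test_that("the empty augmentation menu is the identity", {
  p <- generate_patch(small_params(seed = 41L))
  a <- augment(p, character(0))
  expect_identical(a$image, p$image)
  expect_identical(a$mask, p$mask)
})

test_that("photometric and blur transforms leave the mask untouched", {
  p <- generate_patch(small_params(seed = 42L))
  menu <- c("random_gamma", "random_brightness", "rgb_shift",
            "hue_saturation_value", "color_jitter", "defocus_blur",
            "motion_blur", "gaussian_blur")
  a <- augment(p, menu, seed = 5)
  expect_identical(a$mask, p$mask)
  expect_false(identical(a$image, p$image))
  expect_true(all(a$image >= 0 & a$image <= 1))
})

test_that("geometric transforms keep the mask binary and move it with the image", {
  p <- generate_patch(small_params(seed = 43L))
  menu <- c("shift_scale_rotate", "elastic_transform", "grid_distortion",
            "optical_distortion")
  a <- augment(p, menu, seed = 6)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_equal(dim(a$mask), dim(p$mask))
})

test_that("pure rotation preserves a centred disc's area within 5%", {
  h <- 96L
  mask <- matrix(0, h, h)
  cy <- (h + 1) / 2
  for (i in 1:h) for (j in 1:h) {
    if ((i - cy)^2 + (j - cy)^2 <= 30^2) mask[i, j] <- 1
  }
  patch <- structure(list(image = array(rep(mask, 3), dim = c(h, h, 3L)),
                          mask = mask, origin = NULL,
                          tubule_count = NA_integer_, instances = list(),
                          distractors = list()),
                     class = "annotated_patch")
  for (s in 1:5) {
    a <- augment(patch, "shift_scale_rotate", seed = s,
                 params = list(shift_scale_rotate = list(shift_limit = 0,
                                                         scale_limit = 0)))
    expect_lt(abs(sum(a$mask) - sum(mask)) / sum(mask), 0.05)
  }
})

test_that("fit reduces the training loss on a small phantom set", {
  pp <- small_params()
  ds <- generate_dataset(pp, 16, 0, seed = 51)
  model <- build_model(seg_model_spec("tiny", input_size = 64), seed = 2)
  cfg <- train_config(epochs = 5, lr = 1e-3, batch_size = 4, patience = 5,
                      pad_mode = "none", seed = 3)
  res <- fit(model, ds$train, list(), cfg)
  expect_s3_class(res$log, "tbl_df")
  expect_equal(nrow(res$log), 5L)
  expect_lt(res$log$train_loss[5], res$log$train_loss[1])
  expect_true(all(is.finite(res$log$train_loss)))
  expect_equal(res$stop_reason, "completed")
})

test_that("two fits under identical seeds produce identical logs", {
  pp <- small_params()
  ds <- generate_dataset(pp, 4, 2, seed = 52)
  cfg <- train_config(epochs = 2, lr = 1e-3, batch_size = 2, patience = 2,
                      pad_mode = "reflection",
                      augmentations = c("shift_scale_rotate", "random_gamma"),
                      seed = 9)
  r1 <- fit(build_model(seg_model_spec("tiny", input_size = 64), seed = 4),
            ds$train, ds$val, cfg)
  r2 <- fit(build_model(seg_model_spec("tiny", input_size = 64), seed = 4),
            ds$train, ds$val, cfg)
  expect_identical(r1$log, r2$log)
})

test_that("a constant validation loss stops training after patience + 1 epochs", {
  pp <- small_params()
  ds <- generate_dataset(pp, 2, 1, seed = 53)
  model <- build_model(seg_model_spec("tiny", input_size = 64), seed = 5)
  cfg <- train_config(epochs = 10, lr = 1e-4, batch_size = 2, patience = 1,
                      pad_mode = "none", seed = 1)
  res <- fit(model, ds$train, ds$val, cfg, val_loss_injection = 0.5)
  expect_equal(nrow(res$log), 2L)
  expect_equal(res$stop_reason, "early_stop")
  expect_equal(res$best_epoch, 1L)
})

test_that("the learning rate steps down by lr_factor after lr_step_epoch", {
  pp <- phantom_params(patch_size = 64, n_tubules_range = c(1L, 1L),
                       lumen_radius_range = c(5, 7),
                       ring_thickness_range = c(2, 3), empty_fraction = 0,
                       seed = 61)
  p <- generate_patch(pp)
  p$image <- p$image[1:32, 1:32, , drop = FALSE]
  p$mask <- p$mask[1:32, 1:32]
  model <- build_model(seg_model_spec("tiny", input_size = 32), seed = 6)
  cfg <- train_config(epochs = 32, lr = 1e-4, batch_size = 1, patience = 32,
                      pad_mode = "none", seed = 1)
  res <- fit(model, list(p), list(), cfg)
  expect_equal(res$log$lr[29], 1e-4)
  expect_equal(res$log$lr[30], 1e-4)
  expect_equal(res$log$lr[31], 0.1 * res$log$lr[29])
  expect_equal(res$log$lr[32], 1e-5)
})

test_that("empty training sets are rejected", {
  model <- build_model(seg_model_spec("tiny", input_size = 64), seed = 1)
  expect_error(fit(model, list(), list(), train_config()), "non-empty")
})
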