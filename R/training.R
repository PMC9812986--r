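#' Training configuration
#'
#' Defaults follow the framework's recipe: Adam on mean per-pixel binary
#' cross entropy, 50 epochs, initial learning rate 1e-4, batch size 16,
#' learning rate multiplied by 0.1 after epoch 30, and early stopping
#' when the validation loss has not improved by more than
#' `loss_tolerance` for `patience` consecutive epochs.
#'
#' @param epochs Maximum number of epochs.
#' @param lr Initial learning rate (> 0).
#' @param batch_size Patches per optimisation step (>= 1).
#' @param lr_step_epoch Epoch after which the learning rate is decayed
#'   (a single step; epochs 1..`lr_step_epoch` run at `lr`).
#' @param lr_factor Multiplicative decay factor in (0, 1].
#' @param patience Consecutive non-improving epochs tolerated before
#'   early stop; must not exceed `epochs`.
#' @param loss_tolerance Minimal validation-loss improvement counted as
#'   a change.
#' @param pad_mode Patch-enhancement padding applied to every training
#'   patch (and its mask): `"reflection"`, `"mirror"` or `"none"`.
#' @param margin Mirror-padding band width, pixels.
#' @param augmentations Character subset of [augmentation_menu()].
#' @param loss_on_core If `TRUE`, the loss is restricted to the core
#'   (unpadded) region of the padded canvas; default uses the full
#'   canvas.
#' @param seed Integer seed covering data order and augmentation draws.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 50L, lr = 1e-4, batch_size = 16L,
                         lr_step_epoch = 30L, lr_factor = 0.1,
                         patience = 15L, loss_tolerance = 1e-4,
                         pad_mode = c("reflection", "mirror", "none"),
                         margin = 100L,
                         augmentations = character(0),
                         loss_on_core = FALSE,
                         seed = 1L) {
  pad_mode <- match.arg(pad_mode)
  if (!is.numeric(lr) || lr <= 0) stop("`lr` must be > 0", call. = FALSE)
  if (!is.numeric(lr_factor) || lr_factor <= 0 || lr_factor > 1) {
    stop("`lr_factor` must be in (0, 1]", call. = FALSE)
  }
  if (!is_count(epochs) || epochs < 1) stop("`epochs` must be >= 1", call. = FALSE)
  if (!is_count(batch_size) || batch_size < 1) stop("`batch_size` must be >= 1", call. = FALSE)
  if (!is_count(patience) || patience > epochs) {
    stop("`patience` must be a count <= epochs", call. = FALSE)
  }
  bad <- setdiff(augmentations, augmentation_menu())
  if (length(bad) > 0) {
    stop("unknown augmentation(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 lr_step_epoch = as.integer(lr_step_epoch),
                 lr_factor = lr_factor, patience = as.integer(patience),
                 loss_tolerance = loss_tolerance, pad_mode = pad_mode,
                 margin = as.integer(margin),
                 augmentations = as.character(augmentations),
                 loss_on_core = isTRUE(loss_on_core),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' The registered augmentation menu
#'
#' Twelve transforms: four geometric warps (applied identically to image
#' and mask, mask resampled nearest-neighbour so it stays binary), five
#' photometric colour perturbations and three blurs (image only).
#'
#' @return Character vector of transform names.
#' @export
augmentation_menu <- function() {
  c("shift_scale_rotate", "elastic_transform", "grid_distortion",
    "optical_distortion", "random_gamma", "random_brightness", "rgb_shift",
    "hue_saturation_value", "color_jitter", "defocus_blur", "motion_blur",
    "gaussian_blur")
}

geometric_transforms <- function() {
  c("shift_scale_rotate", "elastic_transform", "grid_distortion",
    "optical_distortion")
}

# apply an inverse coordinate map (0-based fractional source coords) to an
# annotated patch: image bilinear, mask nearest
warp_patch <- function(patch, map_r, map_c) {
  patch$image <- clamp01(.warp_sample(patch$image, map_r, map_c, FALSE))
  if (!is.null(patch$mask)) {
    m <- .warp_sample(as_cube(patch$mask), map_r, map_c, TRUE)
    patch$mask <- m[, , 1]
  }
  patch
}

identity_grid <- function(h, w) {
  list(r = matrix(0:(h - 1), h, w), c = matrix(0:(w - 1), h, w, byrow = TRUE))
}

aug_shift_scale_rotate <- function(patch, shift_limit = 0.0625,
                                   scale_limit = 0.1, rotate_limit = 45) {
  d <- dim(patch$image); h <- d[1]; w <- d[2]
  ang <- runif(1, -rotate_limit, rotate_limit) * pi / 180
  s <- 1 + runif(1, -scale_limit, scale_limit)
  sh_r <- runif(1, -shift_limit, shift_limit) * h
  sh_c <- runif(1, -shift_limit, shift_limit) * w
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  g <- identity_grid(h, w)
  dy <- g$r - cy - sh_r; dx <- g$c - cx - sh_c
  map_r <- cy + (cos(ang) * dy + sin(ang) * dx) / s
  map_c <- cx + (-sin(ang) * dy + cos(ang) * dx) / s
  warp_patch(patch, map_r, map_c)
}

aug_elastic <- function(patch, alpha = 6, sigma = 8) {
  d <- dim(patch$image); h <- d[1]; w <- d[2]
  dr <- EBImage::imageData(EBImage::gblur(EBImage::Image(matrix(rnorm(h * w), h, w)), sigma))
  dc <- EBImage::imageData(EBImage::gblur(EBImage::Image(matrix(rnorm(h * w), h, w)), sigma))
  dr <- alpha * dr / max(1e-8, max(abs(dr)))
  dc <- alpha * dc / max(1e-8, max(abs(dc)))
  g <- identity_grid(h, w)
  warp_patch(patch, g$r + dr, g$c + dc)
}

# piecewise-linear 1-d distortion of the sampling grid
grid_axis_map <- function(n, steps, limit) {
  knots_t <- seq(0, n - 1, length.out = steps + 1)
  widths <- diff(knots_t) * (1 + runif(steps, -limit, limit))
  knots_s <- c(0, cumsum(widths))
  knots_s <- knots_s * (n - 1) / knots_s[steps + 1]
  stats::approx(knots_t, knots_s, xout = 0:(n - 1))$y
}

aug_grid_distortion <- function(patch, steps = 5L, limit = 0.3) {
  d <- dim(patch$image); h <- d[1]; w <- d[2]
  mr <- grid_axis_map(h, steps, limit)
  mc <- grid_axis_map(w, steps, limit)
  warp_patch(patch, matrix(mr, h, w), matrix(mc, h, w, byrow = TRUE))
}

aug_optical_distortion <- function(patch, limit = 0.3) {
  d <- dim(patch$image); h <- d[1]; w <- d[2]
  k <- runif(1, -limit, limit)
  cy <- (h - 1) / 2; cx <- (w - 1) / 2
  g <- identity_grid(h, w)
  yn <- (g$r - cy) / cy; xn <- (g$c - cx) / cx
  r2 <- yn^2 + xn^2
  warp_patch(patch, cy + (g$r - cy) * (1 + k * r2), cx + (g$c - cx) * (1 + k * r2))
}

rgb_to_hsv_arr <- function(img) {
  d <- dim(img)
  m <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                                as.vector(img[, , 3])), maxColorValue = 1)
  list(h = m[1, ], s = m[2, ], v = m[3, ], dim = d)
}

hsv_to_rgb_arr <- function(hsv) {
  h6 <- (hsv$h %% 1) * 6
  i <- floor(h6); f <- h6 - i
  v <- hsv$v; s <- hsv$s
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim = hsv$dim)
}

aug_hsv_shift <- function(patch, h_lim = 20 / 360, s_lim = 0.15, v_lim = 0.15) {
  hsv <- rgb_to_hsv_arr(patch$image)
  hsv$h <- hsv$h + runif(1, -h_lim, h_lim)
  hsv$s <- clamp01(hsv$s + runif(1, -s_lim, s_lim))
  hsv$v <- clamp01(hsv$v + runif(1, -v_lim, v_lim))
  patch$image <- clamp01(hsv_to_rgb_arr(hsv))
  patch
}

aug_color_jitter <- function(patch, lim = 0.2, hue_lim = 0.02) {
  img <- patch$image
  img <- img * (1 + runif(1, -lim, lim))                        # brightness
  mu <- mean(img)
  img <- (img - mu) * (1 + runif(1, -lim, lim)) + mu            # contrast
  lum <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  fs <- 1 + runif(1, -lim, lim)                                  # saturation
  for (ch in 1:3) img[, , ch] <- lum + fs * (img[, , ch] - lum)
  patch$image <- clamp01(img)
  hsv <- rgb_to_hsv_arr(patch$image)
  hsv$h <- hsv$h + runif(1, -hue_lim, hue_lim)
  patch$image <- clamp01(hsv_to_rgb_arr(hsv))
  patch
}

blur_with_kernel <- function(img, kern) {
  kern <- kern / sum(kern)
  EBImage::imageData(EBImage::filter2(EBImage::Image(img), kern))
}

motion_kernel <- function(len, angle) {
  k <- matrix(0, len, len)
  c0 <- (len + 1) / 2
  tt <- seq(-(len - 1) / 2, (len - 1) / 2, length.out = 4 * len)
  ri <- pmin(len, pmax(1, round(c0 + tt * sin(angle))))
  ci <- pmin(len, pmax(1, round(c0 + tt * cos(angle))))
  k[cbind(ri, ci)] <- 1
  k
}

#' Apply data augmentations to an annotated patch
#'
#' Each named transform in `menu` is applied once, in order. Geometric
#' warps move image and mask identically (the mask is resampled
#' nearest-neighbour and stays binary); photometric and blur transforms
#' touch the image only.
#'
#' @param patch An `annotated_patch`.
#' @param menu Character vector, a subset of [augmentation_menu()]; the
#'   empty menu is the identity.
#' @param seed Optional seed making the draw reproducible.
#' @param params Optional named list of per-transform argument overrides,
#'   e.g. `list(shift_scale_rotate = list(shift_limit = 0))` for a pure
#'   rotation.
#' @return The transformed `annotated_patch`.
#' @export
augment <- function(patch, menu = character(0), seed = NULL, params = list()) {
  patch <- as_annotated(patch)
  bad <- setdiff(menu, augmentation_menu())
  if (length(bad) > 0) {
    stop("unknown augmentation(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  run <- function() {
    for (tr in menu) {
      xa <- params[[tr]] %||% list()
      patch <- switch(tr,
        shift_scale_rotate = do.call(aug_shift_scale_rotate, c(list(patch), xa)),
        elastic_transform = do.call(aug_elastic, c(list(patch), xa)),
        grid_distortion = do.call(aug_grid_distortion, c(list(patch), xa)),
        optical_distortion = do.call(aug_optical_distortion, c(list(patch), xa)),
        random_gamma = { patch$image <- clamp01(patch$image^runif(1, 0.8, 1.25)); patch },
        random_brightness = { patch$image <- clamp01(patch$image + runif(1, -0.15, 0.15)); patch },
        rgb_shift = {
          for (ch in 1:3) patch$image[, , ch] <- patch$image[, , ch] + runif(1, -0.08, 0.08)
          patch$image <- clamp01(patch$image); patch
        },
        hue_saturation_value = aug_hsv_shift(patch),
        color_jitter = aug_color_jitter(patch),
        defocus_blur = {
          r <- sample(2:4, 1)
          kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
          patch$image <- clamp01(blur_with_kernel(patch$image, kern)); patch
        },
        motion_blur = {
          len <- sample(c(5L, 7L, 9L), 1)
          patch$image <- clamp01(blur_with_kernel(patch$image,
                                                  motion_kernel(len, runif(1, 0, pi))))
          patch
        },
        gaussian_blur = {
          sg <- runif(1, 0.5, 1.5)
          patch$image <- clamp01(EBImage::imageData(
            EBImage::gblur(EBImage::Image(patch$image), sg)))
          patch
        })
    }
    patch
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

dice_binary <- function(pred, truth) {
  denom <- 2 * sum(pred * truth) + sum(pred * (1 - truth)) + sum((1 - pred) * truth)
  if (denom == 0) return(1)
  2 * sum(pred * truth) / (sum(pred) + sum(truth))
}

# pad + resize one patch to the network input; returns x (input tensor),
# y (target mask) and the loss weight plane (core-only when requested)
prep_sample <- function(patch, isz, pad_mode, margin, loss_on_core) {
  padded <- apply_pad(patch, pad_mode, margin)
  d <- dim(padded$image)
  x <- if (d[1] == isz && d[2] == isz) padded$image else resize_image(padded$image, isz)
  y <- padded$mask
  if (is.null(y)) stop("training patches must carry a mask", call. = FALSE)
  if (!all(dim(y) == isz)) y <- resize_image(y, isz, labels = TRUE)
  wgt <- NULL
  if (loss_on_core) {
    cb <- round(padded$core_box * isz / d[1])
    wgt <- matrix(0, isz, isz)
    wgt[(cb[1] + 1):cb[3], (cb[2] + 1):cb[4]] <- 1
  }
  list(x = x, y = y, w = wgt)
}

# loss/gradient evaluated at the logit head (numerically stable BCE)
sample_loss_grad <- function(model, smp) {
  fwd <- nn_forward(model$graph, model$params, smp$x)
  z <- fwd$vals[[model$head_node]][, , 1]
  l <- nn_bce_logits(z, smp$y, smp$w)
  gp <- nn_backward(model$graph, model$params, fwd,
                    array(l$grad, dim = c(dim(z), 1L)),
                    at = model$head_node)
  list(loss = l$loss, gparams = gp)
}

#' Train a segmentation model
#'
#' Minimises mean per-pixel binary cross entropy with Adam. The learning
#' rate is decayed once by `lr_factor` after epoch `lr_step_epoch`;
#' training stops early when the validation loss has not improved by
#' more than `loss_tolerance` for `patience` consecutive epochs. The
#' returned model carries the weights of the best validation-loss epoch
#' (the final weights when no validation set is given).
#'
#' @param model A [build_model()] network.
#' @param train_set Non-empty list of `annotated_patch` with masks.
#' @param val_set List of validation patches (may be empty, which
#'   disables early stopping and best-epoch selection).
#' @param config A [train_config()].
#' @param val_loss_injection Optional numeric vector overriding the
#'   measured validation loss per epoch — a diagnostic hook for
#'   exercising the early-stopping logic with a known loss trajectory.
#' @return A `tubule_fit`: list with the trained `model`, the per-epoch
#'   `log` (tibble: epoch, train_loss, val_loss, val_dsc, lr),
#'   `stop_reason` (`"completed"` or `"early_stop"`) and `best_epoch`.
#' @export
fit <- function(model, train_set, val_set = list(), config = train_config(),
                val_loss_injection = NULL) {
  stopifnot(inherits(model, "seg_model"), inherits(config, "train_config"))
  if (length(train_set) == 0) stop("`train_set` must be non-empty", call. = FALSE)
  isz <- model$spec$input_size
  set.seed(config$seed)

  static_aug <- length(config$augmentations) == 0
  prep_all <- function(patches, augment_now) {
    lapply(patches, function(p) {
      if (augment_now) p <- augment(p, config$augmentations)
      prep_sample(p, isz, config$pad_mode, config$margin, config$loss_on_core)
    })
  }
  train_prep <- if (static_aug) prep_all(train_set, FALSE) else NULL
  val_prep <- prep_all(val_set, FALSE)

  opt <- adam_init(model$params)
  n <- length(train_set)
  log <- vector("list", config$epochs)
  best_loss <- Inf; best_epoch <- NA_integer_; best_params <- NULL
  bad <- 0L; stop_reason <- "completed"

  for (epoch in seq_len(config$epochs)) {
    lr_e <- config$lr * if (epoch > config$lr_step_epoch) config$lr_factor else 1
    samples <- if (static_aug) train_prep else prep_all(train_set, TRUE)
    ord <- sample.int(n)
    epoch_losses <- numeric(0)
    for (b0 in seq(1, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      gacc <- NULL
      for (i in idx) {
        r <- sample_loss_grad(model, samples[[i]])
        epoch_losses <- c(epoch_losses, r$loss)
        gacc <- if (is.null(gacc)) r$gparams else {
          Map(`+`, gacc, r$gparams)
        }
      }
      gacc <- lapply(gacc, function(g) g / length(idx))
      st <- adam_step(model$params, gacc, opt, lr_e)
      model$params <- st$params
      opt <- st$state
    }

    val_loss <- NA_real_; val_dsc <- NA_real_
    if (length(val_prep) > 0) {
      vl <- vapply(val_prep, function(s) {
        p <- nn_forward(model$graph, model$params, s$x)$out[, , 1]
        c(nn_bce(p, s$y)$loss, dice_binary(binarize(p), s$y))
      }, numeric(2))
      val_loss <- mean(vl[1, ]); val_dsc <- mean(vl[2, ])
      if (!is.null(val_loss_injection)) {
        val_loss <- val_loss_injection[min(epoch, length(val_loss_injection))]
      }
    }
    log[[epoch]] <- tibble::tibble(epoch = epoch,
                                   train_loss = mean(epoch_losses),
                                   val_loss = val_loss, val_dsc = val_dsc,
                                   lr = lr_e)
    if (length(val_prep) > 0) {
      if (val_loss < best_loss - config$loss_tolerance) {
        best_loss <- val_loss; best_epoch <- epoch
        best_params <- model$params; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) { stop_reason <- "early_stop"; break }
      }
    }
  }

  if (!is.null(best_params)) model$params <- best_params
  if (is.na(best_epoch)) best_epoch <- length(Filter(Negate(is.null), log))
  structure(list(model = model,
                 log = do.call(rbind, Filter(Negate(is.null), log)),
                 stop_reason = stop_reason, best_epoch = best_epoch,
                 config = config),
            class = "tubule_fit")
}

#' @export
print.tubule_fit <- function(x, ...) {
  cat(sprintf("<tubule_fit> %d epoch(s), stop=%s, best_epoch=%d\n",
              nrow(x$log), x$stop_reason, x$best_epoch))
  print(utils::tail(x$log, 3))
  invisible(x)
}
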