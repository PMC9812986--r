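#' Desk-scale learning benchmark on synthetic phantoms
#'
#' Trains the `tiny` backbone on a small phantom dataset (64 training and
#' 16 held-out patches of 128 px by default, geometry scaled from the
#' 900-px defaults) for at most 15 epochs on CPU, then scores the
#' held-out patches. The optimiser recipe (learning rate 2e-3, batch
#' size 4) gives the run enough optimisation steps inside the epoch cap;
#' all randomness (data, weight initialisation, batch order) derives
#' from the single `seed`.
#'
#' @param seed Master integer seed.
#' @param n_train,n_val Number of training / held-out phantom patches.
#' @param patch_size Phantom patch side in pixels.
#' @param epochs Epoch cap.
#' @return List with the `tubule_fit`, per-patch held-out reports
#'   (tibble), and the pooled (`dsc_micro`) and per-patch-averaged
#'   (`dsc_macro`) held-out Dice coefficients.
#' @export
learning_benchmark <- function(seed = 1L, n_train = 64L, n_val = 16L,
                               patch_size = 128L, epochs = 15L) {
  set.seed(seed)
  s <- sample.int(2^30, 3)
  pp <- scaled_phantom_params(patch_size)
  ds <- generate_dataset(pp, n_train, n_val, seed = s[1])
  model <- build_model(seg_model_spec("tiny", input_size = patch_size),
                       seed = s[2])
  cfg <- train_config(epochs = epochs, lr = 2e-3, batch_size = 4L,
                      patience = epochs, pad_mode = "none", seed = s[3])
  res <- fit(model, ds$train, ds$val, cfg)
  reports <- lapply(ds$val, function(p) {
    score(binarize(predict_patch(res$model, p, pad_mode = "none")), p$mask)
  })
  list(fit = res,
       reports = do.call(rbind, reports),
       dsc_micro = aggregate_scores(reports, "micro")$dsc,
       dsc_macro = aggregate_scores(reports, "macro")$dsc,
       n_train = n_train, n_val = n_val)
}

#' Directional effect of reflection padding on incomplete-tubule phantoms
#'
#' Trains matched models (same data, initialisation and budget) with
#' reflection padding and without padding on phantoms whose tubules are
#' predominantly truncated at patch edges (`incomplete_fraction = 0.8`),
#' and compares pooled held-out Dice per arm. Tubule geometry is kept
#' coarse enough (about 2/7 of the full-size scale on 128-px patches)
#' that structures remain several pixels wide after the reflection arm's
#' two-fold downsample, so the comparison probes boundary completion
#' rather than resolution loss. Each model is evaluated with its own
#' padding mode at prediction time.
#'
#' @param seeds Integer vector of master seeds (one matched pair each).
#' @param n_train,n_val Phantom counts per split.
#' @param epochs Training budget per arm.
#' @return List with a per-run tibble (`runs`: seed, pad_mode, dsc), the
#'   per-arm means, and `delta` = mean(reflection) - mean(none).
#' @export
padding_effect_benchmark <- function(seeds = 1:3, n_train = 24L, n_val = 8L,
                                     epochs = 12L) {
  params <- phantom_params(patch_size = 128L,
                           lumen_radius_range = c(30, 80) * 256 / 900,
                           ring_thickness_range = c(12, 22) * 256 / 900,
                           incomplete_fraction = 0.8)
  arm <- function(pad_mode, s) {
    ds <- generate_dataset(params, n_train, n_val, seed = s[1])
    model <- build_model(seg_model_spec("tiny", input_size = 128L), seed = s[2])
    cfg <- train_config(epochs = epochs, lr = 2e-3, batch_size = 2L,
                        patience = epochs, pad_mode = pad_mode, seed = s[3])
    res <- fit(model, ds$train, ds$val, cfg)
    reps <- lapply(ds$val, function(p) {
      score(binarize(predict_patch(res$model, p, pad_mode = pad_mode)), p$mask)
    })
    aggregate_scores(reps, "micro")$dsc
  }
  rows <- list()
  for (sd in seeds) {
    set.seed(sd)
    s <- sample.int(2^30, 3)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      seed = sd, pad_mode = "reflection", dsc = arm("reflection", s))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      seed = sd, pad_mode = "none", dsc = arm("none", s))
  }
  runs <- do.call(rbind, rows)
  mean_ref <- mean(runs$dsc[runs$pad_mode == "reflection"])
  mean_none <- mean(runs$dsc[runs$pad_mode == "none"])
  list(runs = runs, mean_reflection = mean_ref, mean_none = mean_none,
       delta = mean_ref - mean_none)
}
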