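# Shared fixtures: small phantom parameter sets and a cached tiny model so
# expensive builds run once per session.

small_params <- function(seed = 1L, incomplete_fraction = 0.2, ...) {
  phantom_params(patch_size = 64, n_tubules_range = c(1L, 3L),
                 lumen_radius_range = c(5, 9), ring_thickness_range = c(2, 4),
                 incomplete_fraction = incomplete_fraction,
                 distractor_count_range = c(0L, 1L),
                 empty_fraction = 0, seed = seed, ...)
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

tiny_model_64 <- function() {
  cached("tiny64", build_model(seg_model_spec("tiny", input_size = 64), seed = 3L))
}

# independent nested-loop pixel-counting oracle for score()
oracle_score <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; t <- truth[i, j]
      if (p == 1 && t == 1) tp <- tp + 1L
      else if (p == 1 && t == 0) fp <- fp + 1L
      else if (p == 0 && t == 0) tn <- tn + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       dsc = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
       recall = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
       specificity = if (fp + tn > 0) 100 * tn / (fp + tn) else NA_real_)
}

# independent point-in-ellipse test (pixel centre at integer coordinates)
oracle_in_ellipse <- function(y, x, inst) {
  dy <- y - inst$center[1]; dx <- x - inst$center[2]
  u <- dx * cos(inst$theta) + dy * sin(inst$theta)
  v <- -dx * sin(inst$theta) + dy * cos(inst$theta)
  (u / (inst$a + inst$ring))^2 + (v / (inst$b + inst$ring))^2 <= 1
}
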