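# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a stream of child seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  if (n == 0L) return(integer(0))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == round(x)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[1] > x[2]) {
    stop(sprintf("`%s` must be a numeric range c(min, max) with min <= max", name),
         call. = FALSE)
  }
  invisible(x)
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Force an image to an H x W x 3 array in [0, 1].
as_rgb <- function(img) {
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (length(dim(img)) != 3L) stop("expected an H x W x 3 image array", call. = FALSE)
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), dim = c(dim(img)[1:2], 3L))
  if (dim(img)[3] != 3L) stop("expected 1, 3 or 4 channels", call. = FALSE)
  img
}

check_binary_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be an H x W matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1))) stop("mask values must be in {0, 1}", call. = FALSE)
  invisible(mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fold a 0-based index vector into [0, n) by reflection without repeating the
# edge sample (period 2n - 2); n == 1 maps everything to 0.
fold_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * n - 2L
  i <- i %% p
  ifelse(i >= n, p - i, i)
}
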