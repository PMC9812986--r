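#' Parameters for the synthetic tubule phantom generator
#'
#' The phantom generator draws H&E-like RGB patches containing elliptical
#' tubules (a pale lumen ringed by dark epithelial nuclei) over a pink
#' stromal background, together with a pixel-perfect binary ground-truth
#' mask. Lumen-bearing distractors (thin-walled vessel-like rings and
#' white adipocyte-like blobs) are painted into the image but never into
#' the mask, so false-positive behaviour of a segmentation model can be
#' probed. Colours are flat fills plus Gaussian channel noise; the
#' generator makes no attempt at photorealistic staining.
#'
#' @param patch_size Side length of a generated square patch, in pixels
#'   (at an appearance comparable to a 20x scan); must be >= 64.
#' @param n_tubules_range Inclusive integer range for the number of
#'   tubules in a non-empty patch.
#' @param lumen_radius_range Range of the lumen semi-major axis, pixels.
#' @param ring_thickness_range Range of the nuclear ring thickness, pixels.
#' @param incomplete_fraction Proportion of tubules whose centre is placed
#'   within one lumen radius of a patch edge, so the structure is
#'   truncated ("incomplete"); in \[0, 1\].
#' @param distractor_count_range Integer range for the number of
#'   vessel-like / adipocyte-like non-tubule structures.
#' @param empty_fraction Probability that a patch contains no tubules at
#'   all (class balance of tubule-free patches).
#' @param stain_palette Named list of RGB triples on the 0-255 scale:
#'   `background`, `lumen`, `nucleus`.
#' @param noise_sd Standard deviation of additive per-channel Gaussian
#'   noise, on the 0-255 scale.
#' @param placement `"random"` places tubules independently; `"spaced"`
#'   rejects placements whose bounding circles overlap an earlier tubule,
#'   so instances stay disjoint when geometry permits.
#' @param seed Integer seed; identical parameters (same seed) give
#'   bit-identical patches. `NULL` draws from the current RNG stream.
#'
#' @return A validated parameter list of class `phantom_params`.
#' @seealso [generate_patch()], [generate_dataset()], [generate_large_image()]
#' @export
phantom_params <- function(patch_size = 900L,
                           n_tubules_range = c(2L, 6L),
                           lumen_radius_range = c(30, 80),
                           ring_thickness_range = c(12, 22),
                           incomplete_fraction = 0.3,
                           distractor_count_range = c(0L, 3L),
                           empty_fraction = 0.2,
                           stain_palette = list(
                             background = c(231, 183, 207),
                             lumen = c(245, 243, 245),
                             nucleus = c(72, 40, 110)
                           ),
                           noise_sd = 4,
                           placement = c("random", "spaced"),
                           seed = NULL) {
  if (!is_count(patch_size) || patch_size < 64) {
    stop("`patch_size` must be a single integer >= 64", call. = FALSE)
  }
  check_range(n_tubules_range, "n_tubules_range")
  check_range(lumen_radius_range, "lumen_radius_range")
  check_range(ring_thickness_range, "ring_thickness_range")
  check_range(distractor_count_range, "distractor_count_range")
  if (any(n_tubules_range < 0) || any(distractor_count_range < 0)) {
    stop("count ranges must be non-negative", call. = FALSE)
  }
  if (any(lumen_radius_range <= 0) || any(ring_thickness_range <= 0)) {
    stop("geometry ranges must be positive", call. = FALSE)
  }
  if (!is.numeric(incomplete_fraction) || incomplete_fraction < 0 ||
      incomplete_fraction > 1) {
    stop("`incomplete_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(empty_fraction) || empty_fraction < 0 || empty_fraction > 1) {
    stop("`empty_fraction` must be in [0, 1]", call. = FALSE)
  }
  stopifnot(all(c("background", "lumen", "nucleus") %in% names(stain_palette)))
  placement <- match.arg(placement)
  structure(list(
    patch_size = as.integer(patch_size),
    n_tubules_range = as.integer(round(n_tubules_range)),
    lumen_radius_range = as.numeric(lumen_radius_range),
    ring_thickness_range = as.numeric(ring_thickness_range),
    incomplete_fraction = incomplete_fraction,
    distractor_count_range = as.integer(round(distractor_count_range)),
    empty_fraction = empty_fraction,
    stain_palette = lapply(stain_palette, as.numeric),
    noise_sd = as.numeric(noise_sd),
    placement = placement,
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "phantom_params")
}

# 1-based linear indices of pixels whose integer-coordinate centre lies
# inside the rotated ellipse (cy, cx, semi-axes a >= along theta, b).
ellipse_indices <- function(h, w, cy, cx, a, b, theta) {
  r <- max(a, b)
  i0 <- max(1L, floor(cy - r)); i1 <- min(h, ceiling(cy + r))
  j0 <- max(1L, floor(cx - r)); j1 <- min(w, ceiling(cx + r))
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  dy <- matrix(ii - cy, length(ii), length(jj))
  dx <- matrix(jj - cx, length(ii), length(jj), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx_i <- matrix(ii, length(ii), length(jj))
  idx_j <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  (idx_i + (idx_j - 1L) * h)[inside]
}

paint <- function(img, idx, rgb01) {
  if (length(idx) == 0L) return(img)
  hw <- dim(img)[1] * dim(img)[2]
  for (ch in 1:3) img[idx + (ch - 1L) * hw] <- rgb01[ch]
  img
}

# Draw one tubule scene on an h x w canvas using the current RNG stream.
# Counts are supplied by the caller so patch- and large-image generation
# share one code path.
scene_generate <- function(params, h, w, n_tubules, n_distractors) {
  pal <- lapply(params$stain_palette, function(p) p / 255)
  img <- array(rep(pal$background, each = h * w), dim = c(h, w, 3L))
  mask <- matrix(0, h, w)
  instances <- list()
  ring_base <- 0.45 * pal$nucleus + 0.55 * pal$background

  if (n_tubules > 0) {
    for (k in seq_len(n_tubules)) {
      lr <- params$lumen_radius_range
      rt <- params$ring_thickness_range
      for (try in 1:200) {
        a <- runif(1, lr[1], lr[2])
        b <- a * runif(1, 0.6, 1)
        t <- runif(1, rt[1], rt[2])
        theta <- runif(1, 0, pi)
        rout <- a + t
        if (runif(1) < params$incomplete_fraction) {
          # centre within one lumen radius of an edge, and close enough that
          # the footprint (minor outer semi-axis b + t) always crosses it
          edge <- sample(1:4, 1)
          d <- runif(1, 0, min(a, b + t - 1))
          cy <- switch(edge, d, h - d, runif(1, 1, h), runif(1, 1, h))
          cx <- switch(edge, runif(1, 1, w), runif(1, 1, w), d, w - d)
        } else {
          lo <- rout + 2; hi_y <- h - rout - 1; hi_x <- w - rout - 1
          if (hi_y <= lo || hi_x <= lo) {
            cy <- runif(1, 1, h); cx <- runif(1, 1, w)
          } else {
            cy <- runif(1, lo, hi_y); cx <- runif(1, lo, hi_x)
          }
        }
        ok <- TRUE
        if (params$placement == "spaced" && length(instances) > 0) {
          for (inst in instances) {
            sep <- sqrt((cy - inst$center[1])^2 + (cx - inst$center[2])^2)
            if (sep < rout + inst$a + inst$ring + 2) { ok <- FALSE; break }
          }
        }
        if (ok) break
      }
      inst <- list(center = c(cy, cx), a = a, b = b, theta = theta, ring = t)
      instances[[k]] <- inst

      outer_idx <- ellipse_indices(h, w, cy, cx, a + t, b + t, theta)
      lumen_idx <- ellipse_indices(h, w, cy, cx, a, b, theta)
      mask[outer_idx] <- 1
      img <- paint(img, outer_idx, ring_base)
      img <- paint(img, lumen_idx, pal$lumen)
      # ring of nucleus-coloured discs with jittered centres
      am <- a + t / 2; bm <- b + t / 2
      per <- 2 * pi * sqrt((am^2 + bm^2) / 2)
      nd <- max(6L, round(per / max(3, 0.9 * t)))
      ang <- seq(0, 2 * pi, length.out = nd + 1)[-1] + runif(nd, -0.1, 0.1)
      for (q in seq_len(nd)) {
        px <- am * cos(ang[q]); py <- bm * sin(ang[q])
        dcx <- cx + px * cos(theta) - py * sin(theta) + runif(1, -t / 6, t / 6)
        dcy <- cy + px * sin(theta) + py * cos(theta) + runif(1, -t / 6, t / 6)
        dr <- (t / 2) * runif(1, 0.7, 1.05)
        disc <- ellipse_indices(h, w, dcy, dcx, dr, dr, 0)
        # nuclei live inside the annulus: clip discs to the mask support
        disc <- disc[mask[disc] == 1]
        img <- paint(img, disc, pal$nucleus)
      }
    }
  }

  distractors <- list()
  if (n_distractors > 0) {
    mlr <- mean(params$lumen_radius_range)
    for (k in seq_len(n_distractors)) {
      type <- sample(c("vessel", "adipocyte"), 1)
      cy <- runif(1, 1, h); cx <- runif(1, 1, w)
      theta <- runif(1, 0, pi)
      if (type == "vessel") {
        a <- runif(1, 0.35, 0.8) * mlr; b <- a * runif(1, 0.5, 0.9); t <- 2
        wall <- c(150, 60, 80) / 255          # thin endothelial wall
        outer_idx <- ellipse_indices(h, w, cy, cx, a + t, b + t, theta)
        inner_idx <- ellipse_indices(h, w, cy, cx, a, b, theta)
        img <- paint(img, outer_idx, wall)
        img <- paint(img, inner_idx, pal$lumen)
      } else {
        a <- runif(1, 0.5, 1.1) * mlr; b <- a * runif(1, 0.8, 1); t <- 1.5
        membrane <- c(200, 170, 190) / 255    # faint cytoplasmic membrane
        outer_idx <- ellipse_indices(h, w, cy, cx, a + t, b + t, theta)
        inner_idx <- ellipse_indices(h, w, cy, cx, a, b, theta)
        img <- paint(img, outer_idx, membrane)
        img <- paint(img, inner_idx, c(250, 248, 250) / 255)
      }
      distractors[[k]] <- list(type = type, center = c(cy, cx), a = a, b = b,
                               theta = theta, wall = t)
    }
  }

  if (params$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, params$noise_sd / 255)
    img <- clamp01(img)
  }

  structure(list(
    image = img,
    mask = mask,
    origin = NULL,
    tubule_count = n_tubules,
    instances = instances,
    distractors = distractors
  ), class = "annotated_patch")
}

draw_count <- function(range, empty_fraction = 0) {
  if (empty_fraction > 0 && runif(1) < empty_fraction) return(0L)
  if (range[1] == range[2]) return(range[1])
  sample(seq(range[1], range[2]), 1)
}

#' Generate one synthetic annotated tubule patch
#'
#' @param params A [phantom_params()] object.
#' @return An `annotated_patch`: list with `image` (H x W x 3 array in
#'   \[0, 1\]), `mask` (H x W matrix over \{0, 1\}, 1 = tubule pixel),
#'   `origin` (row/col in a parent image, or `NULL`), `tubule_count`
#'   (number of generated instances, not connected components), plus the
#'   per-instance geometry under `instances` and `distractors`.
#' @examples
#' p <- generate_patch(phantom_params(patch_size = 128,
#'   lumen_radius_range = c(8, 16), ring_thickness_range = c(3, 6), seed = 1))
#' p$tubule_count
#' @export
generate_patch <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  gen <- function() {
    n <- draw_count(params$n_tubules_range, params$empty_fraction)
    nd <- draw_count(params$distractor_count_range)
    scene_generate(params, params$patch_size, params$patch_size, n, nd)
  }
  if (is.null(params$seed)) gen() else with_seed(params$seed, gen())
}

#' Generate seeded training and validation phantom datasets
#'
#' Child seeds for the two splits are drawn from one master seed as
#' disjoint streams, so the train and validation patches are independent
#' yet fully reproducible.
#'
#' @param params A [phantom_params()] object (its own `seed` is ignored).
#' @param n_train,n_val Number of patches per split.
#' @param seed Master integer seed.
#' @return A list with elements `train` and `val`, each a list of
#'   `annotated_patch` objects.
#' @export
generate_dataset <- function(params, n_train, n_val, seed = 1L) {
  stopifnot(inherits(params, "phantom_params"))
  if (!is_count(n_train) || !is_count(n_val)) {
    stop("`n_train` and `n_val` must be non-negative counts", call. = FALSE)
  }
  seeds <- derive_seeds(seed, n_train + n_val)
  make <- function(s) {
    p <- params; p$seed <- s
    generate_patch(p)
  }
  list(
    train = lapply(seeds[seq_len(n_train)], make),
    val = lapply(seeds[n_train + seq_len(n_val)], make)
  )
}

#' Generate a large annotated phantom image
#'
#' Produces one image larger than a single patch (standing in for a
#' cropped whole-slide region) so the overlap tiling and stitching
#' pipeline can be exercised; tubules may straddle future tile borders.
#' Tubule and distractor counts scale with the area relative to
#' `patch_size^2`.
#'
#' @inheritParams generate_patch
#' @param height,width Output dimensions in pixels; both must be at least
#'   `params$patch_size`.
#' @return An `annotated_patch` of size `height` x `width`.
#' @export
generate_large_image <- function(params, height, width) {
  stopifnot(inherits(params, "phantom_params"))
  if (!is_count(height) || !is_count(width) ||
      height < params$patch_size || width < params$patch_size) {
    stop("`height` and `width` must be >= patch_size", call. = FALSE)
  }
  gen <- function() {
    blocks <- ceiling(height * width / params$patch_size^2)
    n <- sum(vapply(seq_len(blocks), function(i) {
      draw_count(params$n_tubules_range, params$empty_fraction)
    }, numeric(1)))
    nd <- sum(vapply(seq_len(blocks), function(i) {
      draw_count(params$distractor_count_range)
    }, numeric(1)))
    scene_generate(params, as.integer(height), as.integer(width), n, nd)
  }
  if (is.null(params$seed)) gen() else with_seed(params$seed, gen())
}

#' Phantom parameters geometrically scaled to a smaller patch size
#'
#' Scales the default lumen-radius and ring-thickness ranges in
#' proportion to `patch_size / 900`, so patches generated at reduced
#' resolution keep the same tubule-to-patch geometry as the full-size
#' defaults. Any other [phantom_params()] argument can be overridden via
#' `...`.
#'
#' @param patch_size Target patch side in pixels (>= 64).
#' @param ... Overrides passed on to [phantom_params()].
#' @return A `phantom_params` object.
#' @export
scaled_phantom_params <- function(patch_size, ...) {
  s <- patch_size / 900
  defaults <- list(patch_size = patch_size,
                   lumen_radius_range = pmax(2, c(30, 80) * s),
                   ring_thickness_range = pmax(1.5, c(12, 22) * s))
  phantom_params(patch_size = patch_size,
                 lumen_radius_range = defaults$lumen_radius_range,
                 ring_thickness_range = defaults$ring_thickness_range,
                 ...)
}

#' @export
print.annotated_patch <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<annotated_patch> %d x %d, %d tubule instance(s), %d distractor(s), %.1f%% tubule pixels\n",
              d[1], d[2], x$tubule_count, length(x$distractors),
              100 * mean(x$mask)))
  invisible(x)
}
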