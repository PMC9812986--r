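#' Overlap tiling of large images
#'
#' Images larger than one patch are processed as a grid of core cells,
#' each extracted together with a context band taken from its neighbours
#' (25% of the core per side by default, so a 900-pixel core yields a
#' 1350-pixel tile). The parent is conceptually extended by reflection so
#' every tile is full size, including at the borders; after per-tile
#' prediction the maps are stitched back so each parent pixel is covered.
#'
#' @name tiling
NULL

#' Plan an overlap tile grid over a parent image
#'
#' @param parent_height,parent_width Parent image dimensions in pixels.
#' @param core Side of the core cell each tile is responsible for
#'   (default 900).
#' @param overlap_fraction Fraction of `core` taken from each neighbour
#'   per side; in \[0, 0.5\] and such that `core * overlap_fraction` is an
#'   integer. The tile side is `core * (1 + 2 * overlap_fraction)`.
#' @return A `tile_plan` with the tile/band geometry, the reflection
#'   border sizes, and row-major 0-based tile origins in padded-parent
#'   coordinates.
#' @export
plan_tiles <- function(parent_height, parent_width, core = 900L,
                       overlap_fraction = 0.25) {
  if (!is_count(parent_height) || !is_count(parent_width) ||
      parent_height < 1 || parent_width < 1) {
    stop("parent dimensions must be positive integers", call. = FALSE)
  }
  if (!is_count(core) || core < 1) stop("`core` must be a positive integer", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction > 0.5) {
    stop("`overlap_fraction` must be in [0, 0.5]", call. = FALSE)
  }
  band <- core * overlap_fraction
  if (abs(band - round(band)) > 1e-9) {
    stop("`core * overlap_fraction` must be an integer number of pixels",
         call. = FALSE)
  }
  band <- as.integer(round(band))
  core <- as.integer(core)
  h <- as.integer(parent_height); w <- as.integer(parent_width)
  n_rows <- ceiling(h / core)
  n_cols <- ceiling(w / core)
  origins <- as.matrix(expand.grid(
    row = (seq_len(n_rows) - 1L) * core,
    col = (seq_len(n_cols) - 1L) * core
  ))
  origins <- origins[order(origins[, "row"], origins[, "col"]), , drop = FALSE]
  structure(list(
    parent_height = h, parent_width = w,
    core = core, overlap_fraction = overlap_fraction,
    tile = core + 2L * band, band = band,
    border_pad = c(top = band, left = band,
                   bottom = band + n_rows * core - h,
                   right = band + n_cols * core - w),
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    origins = origins
  ), class = "tile_plan")
}

#' @export
print.tile_plan <- function(x, ...) {
  cat(sprintf("<tile_plan> parent %d x %d, core %d, tile %d (overlap %.0f%%), %d x %d tiles\n",
              x$parent_height, x$parent_width, x$core, x$tile,
              100 * x$overlap_fraction, x$n_rows, x$n_cols))
  invisible(x)
}

# Extend a plane by reflection on each side (sizes may differ per side);
# indices fold with period 2n-2 so any border size is defined.
reflect_extend <- function(m, top, bottom, left, right) {
  h <- dim(m)[1]; w <- dim(m)[2]
  ri <- fold_index((-top):(h + bottom - 1L), h) + 1L
  ci <- fold_index((-left):(w + right - 1L), w) + 1L
  pad_plane(m, ri, ci)
}

#' Extract the planned tiles from a parent image
#'
#' @param parent An `annotated_patch` or image array matching the plan's
#'   parent dimensions.
#' @param plan A [plan_tiles()] plan.
#' @return List of `annotated_patch` tiles (image plus mask when the
#'   parent carries one), each of side `plan$tile`, with its `origin` set
#'   to the tile's 0-based top-left in padded-parent coordinates.
#' @export
extract_tiles <- function(parent, plan) {
  stopifnot(inherits(plan, "tile_plan"))
  parent <- as_annotated(parent)
  d <- dim(parent$image)
  if (d[1] != plan$parent_height || d[2] != plan$parent_width) {
    stop("parent dimensions do not match the tile plan", call. = FALSE)
  }
  bp <- plan$border_pad
  img_p <- reflect_extend(parent$image, bp["top"], bp["bottom"], bp["left"], bp["right"])
  mask_p <- if (!is.null(parent$mask)) {
    reflect_extend(parent$mask, bp["top"], bp["bottom"], bp["left"], bp["right"])
  }
  lapply(seq_len(nrow(plan$origins)), function(k) {
    o <- plan$origins[k, ]
    rows <- (o[["row"]] + 1L):(o[["row"]] + plan$tile)
    cols <- (o[["col"]] + 1L):(o[["col"]] + plan$tile)
    structure(list(
      image = pad_plane(img_p, rows, cols),
      mask = if (!is.null(mask_p)) pad_plane(mask_p, rows, cols),
      origin = c(o[["row"]], o[["col"]]),
      tubule_count = NA_integer_, instances = list(), distractors = list()
    ), class = "annotated_patch")
  })
}

#' Stitch per-tile probability maps back into a parent-sized map
#'
#' @param tiles List of tile probability maps (square matrices of side
#'   `plan$tile`) in plan order, e.g. the per-tile model outputs.
#' @param plan The [plan_tiles()] plan the tiles were extracted with.
#' @param blend `"core_crop"` pastes each tile's core cell only (every
#'   parent pixel classified by exactly one tile, with full context);
#'   `"mean"` averages all overlapping tile contributions per pixel.
#' @return Probability map matrix of the parent dimensions; values stay
#'   within the range of the inputs.
#' @export
stitch <- function(tiles, plan, blend = c("core_crop", "mean")) {
  stopifnot(inherits(plan, "tile_plan"))
  blend <- match.arg(blend)
  n <- nrow(plan$origins)
  if (length(tiles) != n) {
    stop(sprintf("plan expects %d tiles, got %d", n, length(tiles)), call. = FALSE)
  }
  tiles <- lapply(tiles, function(t) {
    if (inherits(t, "annotated_patch")) t <- t$image
    if (!is.matrix(t) || any(dim(t) != plan$tile)) {
      stop("each tile must be a tile x tile matrix", call. = FALSE)
    }
    t
  })
  h <- plan$parent_height; w <- plan$parent_width
  band <- plan$band; core <- plan$core
  if (blend == "core_crop") {
    out <- matrix(0, h, w)
    for (k in seq_len(n)) {
      o <- plan$origins[k, ]
      r0 <- o[["row"]]; c0 <- o[["col"]]  # core top-left in parent coords
      rows <- (r0 + 1L):min(r0 + core, h)
      cols <- (c0 + 1L):min(c0 + core, w)
      out[rows, cols] <- tiles[[k]][band + seq_along(rows), band + seq_along(cols)]
    }
    return(out)
  }
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (k in seq_len(n)) {
    o <- plan$origins[k, ]
    # tile spans parent rows (o - band) .. (o - band + tile - 1)
    pr <- (o[["row"]] - band):(o[["row"]] - band + plan$tile - 1L)
    pc <- (o[["col"]] - band):(o[["col"]] - band + plan$tile - 1L)
    keep_r <- which(pr >= 0L & pr < h)
    keep_c <- which(pc >= 0L & pc < w)
    rows <- pr[keep_r] + 1L; cols <- pc[keep_c] + 1L
    acc[rows, cols] <- acc[rows, cols] + tiles[[k]][keep_r, keep_c]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  acc / cnt
}
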