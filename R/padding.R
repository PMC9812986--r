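#' Patch-enhancement padding operators
#'
#' Two padding strategies enlarge a training patch so that structures
#' truncated at its edges gain mirrored context: reflection padding tiles
#' the patch with its own flips into a 2x2 canvas of twice the side, and
#' mirror padding reflects a narrow border band outward across each edge.
#' Both return a `padded_patch` that remembers where the original core
#' sits, so [crop_core()] inverts them bit-exactly.
#'
#' @name padding
NULL

as_annotated <- function(x) {
  if (inherits(x, "annotated_patch")) return(x)
  if (is.matrix(x) || (is.array(x) && length(dim(x)) == 3L)) {
    return(structure(list(image = as_rgb(x), mask = NULL, origin = NULL,
                          tubule_count = NA_integer_, instances = list(),
                          distractors = list()),
                     class = "annotated_patch"))
  }
  stop("expected an annotated_patch or an image array", call. = FALSE)
}

pad_plane <- function(m, idx_r, idx_c) {
  if (is.matrix(m)) return(m[idx_r, idx_c, drop = FALSE])
  m[idx_r, idx_c, , drop = FALSE]
}

new_padded <- function(image, mask, mode, core_box, original_size) {
  structure(list(image = image, mask = mask, prob = NULL, mode = mode,
                 core_box = as.integer(core_box),
                 original_size = as.integer(original_size)),
            class = "padded_patch")
}

#' Reflection padding: 2x2 canvas of the patch and its flips
#'
#' The original patch is kept at the top-left; its left-right flip fills
#' the top-right quadrant, its top-bottom flip the bottom-left, and the
#' flip about both axes the bottom-right. Every internal seam therefore
#' mirrors, so no artificial edge is introduced, and a structure cut by a
#' patch border is completed across the seam. The mask, when present, is
#' transformed identically.
#'
#' @param patch An `annotated_patch` (or bare square image array).
#' @return A `padded_patch` whose side is twice the input side;
#'   `core_box` marks the top-left quadrant (0-based, half-open).
#' @export
reflection_pad <- function(patch) {
  patch <- as_annotated(patch)
  d <- dim(patch$image)
  if (d[1] != d[2]) stop("reflection padding requires a square patch", call. = FALSE)
  s <- d[1]
  idx <- c(1:s, s:1)
  image <- pad_plane(patch$image, idx, idx)
  # quadrant assembly written as reflected index lookup: rows/cols 1..s then
  # s..1 reproduce original / LR flip / TB flip / double flip exactly
  mask <- if (!is.null(patch$mask)) pad_plane(patch$mask, idx, idx)
  new_padded(image, mask, "reflection", c(0L, 0L, s, s), s)
}

#' Mirror padding: reflect a border band outward across each edge
#'
#' A band of `margin` pixels adjacent to each side is reflected about the
#' shared edge (without repeating the edge pixel); corners are filled by
#' reflecting about both axes. The original patch sits centred in the
#' enlarged canvas.
#'
#' @param patch An `annotated_patch` (or bare image array).
#' @param margin Band width in pixels; must be smaller than the patch side.
#' @return A `padded_patch` of side `side + 2 * margin` with the centred
#'   core recorded in `core_box`.
#' @export
mirror_pad <- function(patch, margin = 100L) {
  patch <- as_annotated(patch)
  d <- dim(patch$image)
  if (d[1] != d[2]) stop("mirror padding requires a square patch", call. = FALSE)
  s <- d[1]
  margin <- as.integer(margin)
  if (margin < 0 || margin >= s) {
    stop("`margin` must satisfy 0 <= margin < patch side", call. = FALSE)
  }
  idx <- fold_index((-margin):(s + margin - 1L), s) + 1L
  image <- pad_plane(patch$image, idx, idx)
  mask <- if (!is.null(patch$mask)) pad_plane(patch$mask, idx, idx)
  new_padded(image, mask, "mirror", c(margin, margin, margin + s, margin + s), s)
}

no_pad <- function(patch) {
  patch <- as_annotated(patch)
  s <- dim(patch$image)[1]
  new_padded(patch$image, patch$mask, "none", c(0L, 0L, dim(patch$image)[1], dim(patch$image)[2]), s)
}

apply_pad <- function(patch, pad_mode, margin = 100L) {
  switch(pad_mode,
         reflection = reflection_pad(patch),
         mirror = mirror_pad(patch, margin),
         none = no_pad(patch),
         stop(sprintf("unknown pad_mode '%s'", pad_mode), call. = FALSE))
}

#' Recover the original patch from a padded canvas
#'
#' Crops the stored `core_box` out of a `padded_patch`, inverting
#' [reflection_pad()] / [mirror_pad()] bit-exactly for the image, the
#' mask and any attached probability map.
#'
#' @param padded A `padded_patch`.
#' @return An `annotated_patch`; if a probability map is attached it is
#'   cropped alongside as the `prob` element.
#' @export
crop_core <- function(padded) {
  if (!inherits(padded, "padded_patch") || is.null(padded$core_box)) {
    stop("`padded` must be a padded_patch with a core_box", call. = FALSE)
  }
  cb <- padded$core_box
  rows <- (cb[1] + 1L):cb[3]
  cols <- (cb[2] + 1L):cb[4]
  out <- structure(list(
    image = pad_plane(padded$image, rows, cols),
    mask = if (!is.null(padded$mask)) pad_plane(padded$mask, rows, cols),
    origin = NULL, tubule_count = NA_integer_,
    instances = list(), distractors = list()
  ), class = "annotated_patch")
  if (!is.null(padded$prob)) out$prob <- pad_plane(padded$prob, rows, cols)
  out
}

#' Resize an image, probability map or label mask
#'
#' Continuous data (RGB images, probability maps) are resampled with
#' bilinear interpolation; label masks use nearest-neighbour so values
#' stay exactly in \{0, 1\}.
#'
#' @param x Matrix (H x W) or array (H x W x C).
#' @param target Output side length in pixels (square output).
#' @param labels Set `TRUE` for binary masks / label planes.
#' @return Resized matrix or array with the same number of channels.
#' @export
resize_image <- function(x, target, labels = FALSE) {
  if (!is_count(target) || target < 1) stop("`target` must be >= 1", call. = FALSE)
  d <- dim(x)
  if (d[1] == target && d[2] == target && labels) return(x)
  filt <- if (labels) "none" else "bilinear"
  y <- EBImage::imageData(EBImage::resize(EBImage::Image(x), w = target,
                                          h = target, filter = filt))
  if (!labels) {
    rng_lo <- min(x); rng_hi <- max(x)
    y[y < rng_lo] <- rng_lo
    y[y > rng_hi] <- rng_hi
  }
  y
}
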