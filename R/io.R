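#' File input/output and the end-to-end inference workflow
#'
#' Images are handled as PNG or TIFF; masks as single-channel PNG/TIFF
#' with values \{0, 255\}; probability maps persist as 16-bit TIFF with
#' linear \[0, 1\] -> \[0, 65535\] scaling. Polygon annotations use a
#' GeoJSON-style JSON layout. Every command-level output is accompanied
#' by a sidecar JSON recording the package version, configuration and
#' input hashes, so runs are reproducible from their artefacts.
#'
#' @name cli_io
NULL

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext),
       call. = FALSE)
}

#' Read an RGB image
#'
#' PNG and 8/16-bit TIFF are supported; greyscale is replicated to three
#' channels and an alpha channel is dropped. 16-bit TIFF samples are
#' reduced to 8-bit precision by fixed-point scaling
#' `round(v16 * 255 / 65535)` before mapping to \[0, 1\].
#'
#' @param path Image file path.
#' @return H x W x 3 array in \[0, 1\].
#' @export
read_image <- function(path) {
  fmt <- img_format(path)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (fmt == "png") {
    img <- png::readPNG(path)
  } else {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    bits <- attr(raw, "bits.per.sample")
    if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
    img <- if (bits > 8) round(raw * 255 / 65535) / 255 else raw / 255
  }
  as_rgb(img)
}

#' Write an RGB image as PNG or TIFF
#' @param img H x W x 3 array in \[0, 1\].
#' @param path Destination path (extension selects the format).
#' @export
write_image <- function(img, path) {
  img <- clamp01(as_rgb(img))
  if (img_format(path) == "png") png::writePNG(img, path)
  else tiff::writeTIFF(img, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a binary mask
#'
#' The file must be single-channel with values exactly \{0, 255\} (or a
#' multi-channel file whose channels are identical); anything else is
#' rejected.
#'
#' @param path Mask file path (PNG or TIFF).
#' @return H x W matrix over \{0, 1\}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  m <- if (img_format(path) == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) {
    for (ch in seq_len(dim(m)[3])[-1]) {
      if (!identical(m[, , 1], m[, , ch])) {
        stop("mask file has differing channels; expected single-channel {0,255}",
             call. = FALSE)
      }
    }
    m <- m[, , 1]
  }
  vals <- sort(unique(round(as.vector(m) * 255)))
  if (!all(vals %in% c(0, 255))) {
    stop(sprintf("mask values must be {0, 255}; found %s",
                 paste(utils::head(setdiff(vals, c(0, 255)), 5), collapse = ", ")),
         call. = FALSE)
  }
  (m > 0.5) * 1
}

#' Write a binary mask as single-channel PNG/TIFF with values \{0, 255\}
#' @param mask H x W matrix over \{0, 1\}.
#' @param path Destination path.
#' @export
write_mask <- function(mask, path) {
  check_binary_mask(mask)
  if (img_format(path) == "png") png::writePNG(mask, path)
  else tiff::writeTIFF(mask, path, bits.per.sample = 8L)
  invisible(path)
}

#' Persist / load a probability map as 16-bit TIFF
#' @param map Matrix in \[0, 1\].
#' @param path Destination `.tif`/`.tiff` path.
#' @export
write_prob_map <- function(map, path) {
  stopifnot(is.matrix(map))
  tiff::writeTIFF(clamp01(map), path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_prob_map
#' @export
read_prob_map <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m
}

# even-odd (crossing number) scanline rasterization of one polygon at
# pixel centres (x = col - 0.5, y = row - 0.5 in 0-based image coords)
rasterize_polygon <- function(xs, ys, height, width) {
  mask <- matrix(FALSE, height, width)
  n <- length(xs)
  if (n < 3) return(mask)
  for (row in seq_len(height)) {
    y <- row - 0.5
    xcross <- numeric(0)
    for (e in seq_len(n)) {
      x1 <- xs[e]; y1 <- ys[e]
      x2 <- xs[e %% n + 1]; y2 <- ys[e %% n + 1]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        xcross <- c(xcross, x1 + (y - y1) / (y2 - y1) * (x2 - x1))
      }
    }
    if (length(xcross) == 0) next
    xcross <- sort(xcross)
    for (k in seq(1, length(xcross) - 1, by = 2)) {
      cols <- which((seq_len(width) - 0.5) > xcross[k] &
                      (seq_len(width) - 0.5) < xcross[k + 1])
      mask[row, cols] <- !mask[row, cols]  # even-odd fill
    }
  }
  mask
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

polygon_self_intersects <- function(xs, ys) {
  n <- length(xs)
  if (n < 4) return(FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1 || (i == 1 && j == n)) next
      if (segments_intersect(c(xs[i], ys[i]), c(xs[i %% n + 1], ys[i %% n + 1]),
                             c(xs[j], ys[j]), c(xs[j %% n + 1], ys[j %% n + 1]))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rasterize polygon annotations into a binary mask
#'
#' Reads a GeoJSON-style JSON file: an object with `height` and `width`
#' (pixels) and `polygons`, a list of rings given as `[x, y]` vertex
#' pairs in 0-based pixel coordinates. Each polygon interior is filled
#' by the even-odd rule using a pixel-centre inclusion test; overlapping
#' polygons union. A self-intersecting ring raises a warning and is
#' still filled even-odd.
#'
#' @param path JSON annotation file.
#' @return H x W matrix over \{0, 1\}.
#' @export
read_polygons <- function(path) {
  ann <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(ann$height) || is.null(ann$width)) {
    stop("polygon annotation must carry image `height` and `width`", call. = FALSE)
  }
  h <- as.integer(ann$height); w <- as.integer(ann$width)
  mask <- matrix(0, h, w)
  polys <- ann$polygons
  if (is.null(polys) || length(polys) == 0) return(mask)
  for (pg in polys) {
    pg <- do.call(rbind, lapply(pg, function(v) as.numeric(unlist(v))))
    if (is.null(pg) || ncol(pg) != 2) {
      stop("each polygon must be a list of [x, y] vertex pairs", call. = FALSE)
    }
    xs <- pg[, 1]; ys <- pg[, 2]
    if (polygon_self_intersects(xs, ys)) {
      warning("self-intersecting polygon; filling by the even-odd rule",
              call. = FALSE)
    }
    mask[rasterize_polygon(xs, ys, h, w)] <- 1
  }
  mask
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the model specification and weights as an RDS
#' file, with the spec additionally serialised to a YAML sidecar.
#'
#' @param model A `seg_model`.
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(list(spec = unclass(model$spec), params = model$params,
               version = as.character(utils::packageVersion("tubuleseg"))),
          path)
  yaml::write_yaml(unclass(model$spec), paste0(tools::file_path_sans_ext(path),
                                               "_spec.yaml"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  spec <- do.call(seg_model_spec, ck$spec[c("backbone", "input_size",
                                            "encoder_channels",
                                            "decoder_channels", "pretrained")])
  model <- build_model(spec)
  if (!identical(lapply(model$params, dim), lapply(ck$params, dim)) &&
      !identical(lengths(model$params), lengths(ck$params))) {
    stop("checkpoint weights do not match the stored specification", call. = FALSE)
  }
  model$params <- ck$params
  model
}

run_config_fields <- function() {
  c("data_dir", "output_dir", "checkpoint", "model", "train", "core",
    "overlap_fraction", "blend", "pad_mode", "margin", "threshold", "seed",
    "log_level")
}

#' Read / write a run configuration
#'
#' The YAML run configuration mirrors the workflow knobs field-for-field
#' (paths, model spec, training config, tiling parameters, padding mode,
#' threshold, seed, log level); unknown keys are rejected.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_fields())
  if (length(unknown) > 0) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(core = 900L, overlap_fraction = 0.25, blend = "core_crop",
                   pad_mode = "none", margin = 100L, threshold = 0.5,
                   seed = 1L, log_level = "info")
  utils::modifyList(defaults, cfg)
}

#' @rdname read_run_config
#' @param cfg Named list of configuration values.
#' @export
write_run_config <- function(cfg, path) {
  unknown <- setdiff(names(cfg), run_config_fields())
  if (length(unknown) > 0) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

sidecar_json <- function(path, cfg, inputs) {
  info <- list(
    version = as.character(utils::packageVersion("tubuleseg")),
    config = cfg,
    config_hash = unname(tools::md5sum(tempfile_with(cfg))),
    input_hashes = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(info, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

tempfile_with <- function(obj) {
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(obj, tf)
  tf
}

#' Run tiled inference over an image file
#'
#' Plans the overlap tile grid for the image, extracts the tiles, runs
#' the model on each (padding and resizing per the configuration),
#' stitches the per-tile probability maps and thresholds the result.
#' When an output directory is configured, the probability map (16-bit
#' TIFF), the binary mask (PNG) and sidecar JSON provenance files are
#' written there.
#'
#' @param image_path Input image (PNG/TIFF).
#' @param checkpoint Path to a [save_checkpoint()] file, or a
#'   `seg_model` directly.
#' @param config Run configuration list (see [read_run_config()]).
#' @return List with `prob` (parent-sized probability matrix) and
#'   `mask` (binary matrix).
#' @export
run_inference <- function(image_path, checkpoint, config = list()) {
  cfg <- utils::modifyList(
    list(core = 900L, overlap_fraction = 0.25, blend = "core_crop",
         pad_mode = "none", margin = 100L, threshold = 0.5),
    config)
  img <- read_image(image_path)
  model <- if (inherits(checkpoint, "seg_model")) checkpoint else load_checkpoint(checkpoint)
  d <- dim(img)
  if (d[1] <= cfg$core && d[2] <= cfg$core && d[1] == d[2]) {
    prob <- predict_patch(model, img, pad_mode = cfg$pad_mode, margin = cfg$margin)
  } else {
    plan <- plan_tiles(d[1], d[2], core = cfg$core,
                       overlap_fraction = cfg$overlap_fraction)
    tiles <- extract_tiles(img, plan)
    maps <- lapply(tiles, function(t) {
      predict_patch(model, t, pad_mode = cfg$pad_mode, margin = cfg$margin)
    })
    prob <- stitch(maps, plan, blend = cfg$blend)
  }
  mask <- binarize(prob, cfg$threshold)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- tools::file_path_sans_ext(basename(image_path))
    pp <- file.path(cfg$output_dir, paste0(stem, "_prob.tiff"))
    mp <- file.path(cfg$output_dir, paste0(stem, "_mask.png"))
    write_prob_map(prob, pp)
    write_mask(mask, mp)
    sidecar_json(pp, cfg, image_path)
    sidecar_json(mp, cfg, image_path)
  }
  list(prob = prob, mask = mask)
}

#' Write a phantom patch to disk
#'
#' Saves the image (8-bit RGB PNG), the mask (single-channel PNG with
#' values \{0, 255\}) and a JSON sidecar with the generator parameters
#' and per-instance geometry.
#'
#' @param patch An `annotated_patch`.
#' @param dir Output directory (created if needed).
#' @param stem File name stem.
#' @param params Optional [phantom_params()] recorded in the sidecar.
#' @return Invisibly, the image path.
#' @export
write_phantom <- function(patch, dir, stem, params = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(patch$image, file.path(dir, paste0(stem, ".png")))
  write_mask(patch$mask, file.path(dir, paste0(stem, "_mask.png")))
  jsonlite::write_json(
    list(params = if (!is.null(params)) unclass(params),
         tubule_count = patch$tubule_count,
         instances = patch$instances, distractors = patch$distractors),
    file.path(dir, paste0(stem, ".json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, paste0(stem, ".png")))
}
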