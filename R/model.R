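#' Specification of a segmentation network
#'
#' All networks share the U-Net shape: a five-stage encoder whose stage-k
#' feature map has 1/2^k the input's spatial side (strides 2, 4, 8, 16,
#' 32), and a decoder that at each stage upsamples with a 2x2 transposed
#' convolution, concatenates the stride-matched encoder features through
#' a skip connection, and applies two 3x3 convolution + ReLU layers. A
#' 1x1 convolution with sigmoid activation predicts the per-pixel tubule
#' probability. The `basic` backbone is the classic symmetric U-Net
#' encoder (two 3x3 convolutions + ReLU + max-pool per stage); the
#' asymmetric backbones replace it with a classification-style feature
#' hierarchy — residual blocks (`resnet34`), dense bottleneck blocks
#' (`densenet161`) or inverted-bottleneck blocks (`efficientnetb3`) —
#' built here as structurally analogous, randomly initialised encoders
#' (no pretrained weights are distributed). `tiny` is a thin five-stage
#' variant (~0.1M parameters) for CPU-scale work.
#'
#' @param backbone One of `"basic"`, `"tiny"`, `"resnet34"`,
#'   `"densenet161"`, `"efficientnetb3"`.
#' @param input_size Network input side in pixels; must be divisible
#'   by 32 (default 512).
#' @param encoder_channels Optional integer vector of 5 stage widths
#'   overriding the backbone default.
#' @param decoder_channels Widths of the 5 decoder stages (deepest
#'   first).
#' @param pretrained Placeholder flag; pretrained backbone weights are
#'   not available in this package and `TRUE` errors at build time.
#' @return A `seg_model_spec`.
#' @export
seg_model_spec <- function(backbone = c("basic", "tiny", "resnet34",
                                        "densenet161", "efficientnetb3"),
                           input_size = 512L,
                           encoder_channels = NULL,
                           decoder_channels = NULL,
                           pretrained = FALSE) {
  backbone <- match.arg(backbone)
  if (!is_count(input_size) || input_size %% 32 != 0) {
    stop("`input_size` must be a positive multiple of 32", call. = FALSE)
  }
  reg <- backbone_registry()[[backbone]]
  enc <- if (is.null(encoder_channels)) reg$enc else as.integer(encoder_channels)
  if (length(enc) != 5L) stop("`encoder_channels` must have 5 stages", call. = FALSE)
  dec <- if (is.null(decoder_channels)) reg$dec else as.integer(decoder_channels)
  if (length(dec) != 5L) stop("`decoder_channels` must have 5 stages", call. = FALSE)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 encoder_channels = enc, decoder_channels = dec,
                 pretrained = isTRUE(pretrained)),
            class = "seg_model_spec")
}

# Registry of backbone families. Widths/depths are chosen so parameter
# counts order basic < resnet34 < efficientnetb3 < densenet161 within this
# registry.
backbone_registry <- function() {
  list(
    basic = list(type = "conv", stem = 32L,
                 enc = c(64L, 128L, 256L, 512L, 1024L),
                 dec = c(256L, 128L, 64L, 32L, 16L)),
    tiny = list(type = "conv", stem = 8L,
                enc = c(12L, 16L, 24L, 32L, 48L),
                dec = c(32L, 24L, 16L, 12L, 8L)),
    resnet34 = list(type = "res", stem = 64L,
                    enc = c(64L, 128L, 256L, 512L, 512L),
                    units = c(3L, 4L, 6L, 3L, 1L),
                    dec = c(256L, 128L, 64L, 32L, 16L)),
    densenet161 = list(type = "dense", stem = 96L, growth = 48L,
                       layers = c(6L, 12L, 24L, 36L, 24L),
                       enc = c(192L, 384L, 768L, 1024L, 1024L),
                       dec = c(256L, 128L, 64L, 32L, 16L)),
    efficientnetb3 = list(type = "mb", stem = 24L, expand = 3L,
                          blocks = c(2L, 3L, 3L, 4L, 5L),
                          enc = c(32L, 48L, 96L, 136L, 232L),
                          dec = c(256L, 128L, 64L, 32L, 16L))
  )
}

# two 3x3 conv + ReLU layers
enc_block_conv <- function(g, x, cin, cout) {
  g_cr(g, g_cr(g, x, cin, cout), cout, cout)
}

res_unit <- function(g, x, c) {
  h <- g_cr(g, x, c, c)
  h <- g_conv(g, h, c, c)
  g_relu(g, g_sum(g, x, h))
}

dense_block <- function(g, x, cin, layers, growth) {
  cur <- x; c <- cin
  for (l in seq_len(layers)) {
    b <- g_cr(g, cur, c, 4L * growth, k = 1L)
    n <- g_cr(g, b, 4L * growth, growth)
    cur <- g_concat(g, cur, n)
    c <- c + growth
  }
  list(node = cur, c = c)
}

mb_block <- function(g, x, c, e) {
  h <- g_cr(g, x, c, e * c, k = 1L)
  h <- g_cr(g, h, e * c, e * c)
  h <- g_conv(g, h, e * c, c, k = 1L)
  g_sum(g, x, h)
}

# Build the graph for a spec; returns graph + bookkeeping node ids.
build_graph <- function(spec) {
  reg <- backbone_registry()[[spec$backbone]]
  enc <- spec$encoder_channels
  dec <- spec$decoder_channels
  g <- graph_new()
  x <- g_input(g)

  # stride-1 stem (used as the final skip connection)
  stem_c <- reg$stem
  stem <- switch(reg$type,
    conv = enc_block_conv(g, x, 3L, stem_c),
    res = g_cr(g, x, 3L, stem_c),
    dense = g_cr(g, x, 3L, stem_c),
    mb = g_cr(g, x, 3L, stem_c))

  skips <- integer(5)
  skip_c <- integer(5)
  cur <- stem; cur_c <- stem_c
  for (k in 1:5) {
    cur <- g_pool(g, cur)
    if (reg$type == "conv") {
      cur <- enc_block_conv(g, cur, cur_c, enc[k]); cur_c <- enc[k]
    } else if (reg$type == "res") {
      if (cur_c != enc[k]) { cur <- g_cr(g, cur, cur_c, enc[k], k = 1L); cur_c <- enc[k] }
      for (u in seq_len(reg$units[k])) cur <- res_unit(g, cur, cur_c)
    } else if (reg$type == "dense") {
      db <- dense_block(g, cur, cur_c, reg$layers[k], reg$growth)
      cur <- g_cr(g, db$node, db$c, enc[k], k = 1L); cur_c <- enc[k]
    } else if (reg$type == "mb") {
      if (cur_c != enc[k]) { cur <- g_cr(g, cur, cur_c, enc[k], k = 1L); cur_c <- enc[k] }
      for (u in seq_len(reg$blocks[k])) cur <- mb_block(g, cur, cur_c, reg$expand)
    }
    skips[k] <- cur; skip_c[k] <- cur_c
  }

  # decoder: transposed conv upsample, skip concat, two 3x3 conv + ReLU
  dcur <- skips[5]; dcur_c <- skip_c[5]
  skip_nodes <- c(stem, skips[1:4])
  skip_chs <- c(stem_c, skip_c[1:4])
  for (i in 1:5) {
    dcur <- g_convtr(g, dcur, dcur_c, dec[i])
    sk_id <- skip_nodes[6 - i]; sk_c <- skip_chs[6 - i]
    dcur <- g_concat(g, dcur, sk_id)
    dcur <- g_cr(g, dcur, dec[i] + sk_c, dec[i])
    dcur <- g_cr(g, dcur, dec[i], dec[i])
    dcur_c <- dec[i]
  }
  head <- g_conv(g, dcur, dcur_c, 1L, k = 1L)
  out <- g_sigmoid(g, head)
  head_nd <- g$nodes[[head]]
  list(graph = g, input = x, output = out, stages = skips, stem = stem,
       head_node = head, head_params = c(head_nd$w, head_nd$b))
}

#' Build a segmentation model
#'
#' Instantiates the network graph for a [seg_model_spec()] and
#' initialises its weights (He-style, deterministic under `seed`).
#'
#' @param spec A `seg_model_spec`.
#' @param seed Integer seed for weight initialisation.
#' @return A `seg_model` (graph, parameters, spec).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "seg_model_spec"))
  if (spec$pretrained) {
    stop("pretrained backbone weights are not available; build with pretrained = FALSE",
         call. = FALSE)
  }
  gb <- build_graph(spec)
  params <- nn_init_params(gb$graph, seed)
  structure(list(spec = spec, graph = gb$graph, params = params,
                 input = gb$input, output = gb$output,
                 stages = gb$stages, stem = gb$stem,
                 head_node = gb$head_node, head_params = gb$head_params,
                 n_params = nn_count_params(gb$graph)),
            class = "seg_model")
}

#' Count the parameters of a model specification
#'
#' Builds only the graph (no weight allocation), so large backbones can
#' be compared cheaply.
#'
#' @param spec A `seg_model_spec`.
#' @return Total number of trainable scalars.
#' @export
count_model_params <- function(spec) {
  stopifnot(inherits(spec, "seg_model_spec"))
  nn_count_params(build_graph(spec)$graph)
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> backbone=%s input=%d params=%s\n",
              x$spec$backbone, x$spec$input_size,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# raw forward pass on an input_size^2 RGB array -> probability matrix
model_forward <- function(model, x, return_fw = FALSE) {
  d <- dim(x)
  if (d[1] %% 32 != 0 || d[2] %% 32 != 0) {
    stop("network input sides must be divisible by 32", call. = FALSE)
  }
  fw <- nn_forward(model$graph, model$params, x)
  out <- fw$out[, , 1]
  if (return_fw) list(prob = out, fw = fw) else out
}

#' Spatial sizes of the encoder stage feature maps
#'
#' Runs a forward pass and reports the height/width and channel count of
#' each of the five encoder stages (strides 2..32).
#'
#' @param model A `seg_model`.
#' @param x RGB input array (side divisible by 32).
#' @return Tibble with stage, height, width, channels.
#' @export
encoder_feature_shapes <- function(model, x) {
  fw <- nn_forward(model$graph, model$params, as_cube(x))
  info <- t(vapply(model$stages, function(id) dim(fw$vals[[id]]), numeric(3)))
  tibble::tibble(stage = 1:5, height = info[, 1], width = info[, 2],
                 channels = info[, 3])
}

#' Predict a probability map for one patch
#'
#' Applies the configured patch-enhancement padding, downsamples the
#' padded canvas to the network input size, runs the model, upsamples the
#' probability map back to the padded resolution and crops the core, so
#' the result is pixel-aligned with the input patch.
#'
#' @param model A `seg_model`.
#' @param patch `annotated_patch` or H x W x 3 array.
#' @param pad_mode `"reflection"`, `"mirror"` or `"none"`.
#' @param margin Mirror-padding band width (pixels).
#' @return Probability matrix (values in \[0, 1\]) of the patch size.
#' @export
predict_patch <- function(model, patch, pad_mode = c("none", "reflection", "mirror"),
                          margin = 100L) {
  pad_mode <- match.arg(pad_mode)
  patch <- as_annotated(patch)
  padded <- apply_pad(patch, pad_mode, margin)
  d <- dim(padded$image)
  isz <- model$spec$input_size
  if (d[1] == isz && d[2] == isz) {
    prob <- model_forward(model, padded$image)
  } else {
    xin <- resize_image(padded$image, isz)
    prob <- model_forward(model, xin)
    prob <- resize_image(prob, d[1])
  }
  padded$prob <- prob
  crop_core(padded)$prob
}
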