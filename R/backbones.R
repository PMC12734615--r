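# Frozen convolutional feature extractors.
#
# Backbones are flat lists of layer specs interpreted by forward_backbone().
# The two canonical layouts reproduce the published EfficientNetV2-B0 and
# MobileNetV3-Small configurations with classification tops removed; both
# map a 224x224x3 input to a 7x7 activation grid (stride 32). A registry
# allows tiny stub backbones so the fusion/head machinery can be exercised
# in seconds; everything downstream is channel-count agnostic.

layer_conv <- function(k, stride, cin, cout, act = NULL, bn = TRUE,
                       bias = FALSE, zero_dc = FALSE) {
  list(type = "conv", k = k, stride = stride, cin = cin, cout = cout,
       act = act, bn = bn, bias = bias, zero_dc = zero_dc)
}
layer_dwconv <- function(k, stride, ch, act = NULL)
  list(type = "dwconv", k = k, stride = stride, ch = ch, act = act)
layer_se <- function(ch, red, act = "swish", gate = "sigmoid")
  list(type = "se", ch = ch, red = red, act = act, gate = gate)
layer_save <- function() list(type = "save")
layer_add <- function() list(type = "add")

# Parameter arrays for one layer spec (He-normal weights, identity norms).
init_layer <- function(spec) {
  p <- list()
  if (spec$type == "conv") {
    fan_in <- spec$k^2 * spec$cin
    p$w <- array(stats::rnorm(spec$k^2 * spec$cin * spec$cout, 0, sqrt(2 / fan_in)),
                 c(spec$k, spec$k, spec$cin, spec$cout))
    frac_dc <- if (isTRUE(spec$zero_dc)) 1 else as.numeric(spec$zero_dc)
    if (frac_dc > 0) {
      # mean-subtract the filter planes of the first frac*cout output
      # filters: those respond only to edges/texture, never to flat color,
      # while the remaining filters keep their color (DC) response
      sel <- seq_len(round(frac_dc * spec$cout))
      mu <- apply(p$w[, , , sel, drop = FALSE], c(3, 4), mean)
      p$w[, , , sel] <- p$w[, , , sel, drop = FALSE] -
        aperm(array(mu, c(dim(mu), spec$k, spec$k)), c(3, 4, 1, 2))
    }
    if (spec$bias) p$b <- numeric(spec$cout)
    if (spec$bn) {
      p$gamma <- rep(1, spec$cout); p$beta <- numeric(spec$cout)
      p$mean <- numeric(spec$cout); p$var <- rep(1, spec$cout)
    }
  } else if (spec$type == "dwconv") {
    p$w <- array(stats::rnorm(spec$k^2 * spec$ch, 0, sqrt(2 / spec$k^2)),
                 c(spec$k, spec$k, spec$ch))
    p$gamma <- rep(1, spec$ch); p$beta <- numeric(spec$ch)
    p$mean <- numeric(spec$ch); p$var <- rep(1, spec$ch)
  } else if (spec$type == "se") {
    p$w1 <- matrix(stats::rnorm(spec$ch * spec$red, 0, sqrt(2 / spec$ch)), spec$ch, spec$red)
    p$b1 <- numeric(spec$red)
    p$w2 <- matrix(stats::rnorm(spec$red * spec$ch, 0, sqrt(2 / spec$red)), spec$red, spec$ch)
    p$b2 <- numeric(spec$ch)
  }
  p
}

layer_param_count <- function(spec) {
  switch(spec$type,
    conv = spec$k^2 * spec$cin * spec$cout + (if (spec$bias) spec$cout else 0) +
      (if (spec$bn) 4 * spec$cout else 0),
    dwconv = spec$k^2 * spec$ch + 4 * spec$ch,
    se = spec$ch * spec$red + spec$red + spec$red * spec$ch + spec$ch,
    0)
}

# Width helper used by the MobileNetV3 layout: round to a multiple of 8,
# never dropping below 90% of the requested width.
depth8 <- function(v, divisor = 8, min_value = NULL) {
  if (is.null(min_value)) min_value <- divisor
  new_v <- max(min_value, floor(v + divisor / 2) %/% divisor * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

# --- canonical layouts ------------------------------------------------------

# Fused inverted-residual block (early EfficientNetV2 stages, no SE).
fused_mbconv <- function(cin, cout, expand, k = 3, stride = 1) {
  layers <- list()
  residual <- stride == 1 && cin == cout
  if (residual) layers <- c(layers, list(layer_save()))
  if (expand == 1) {
    layers <- c(layers, list(layer_conv(k, stride, cin, cout, act = "swish")))
  } else {
    ce <- cin * expand
    layers <- c(layers, list(layer_conv(k, stride, cin, ce, act = "swish"),
                             layer_conv(1, 1, ce, cout, act = NULL)))
  }
  if (residual) layers <- c(layers, list(layer_add()))
  layers
}

# Inverted residual with depthwise conv and SE (later EfficientNetV2 stages).
mbconv <- function(cin, cout, expand, k = 3, stride = 1, se_ratio = 0.25) {
  ce <- cin * expand
  red <- max(1L, as.integer(cin * se_ratio))
  residual <- stride == 1 && cin == cout
  layers <- list()
  if (residual) layers <- c(layers, list(layer_save()))
  layers <- c(layers, list(
    layer_conv(1, 1, cin, ce, act = "swish"),
    layer_dwconv(k, stride, ce, act = "swish"),
    layer_se(ce, red, act = "swish", gate = "sigmoid"),
    layer_conv(1, 1, ce, cout, act = NULL)))
  if (residual) layers <- c(layers, list(layer_add()))
  layers
}

effnetv2_b0_layers <- function() {
  layers <- list(layer_conv(3, 2, 3, 32, act = "swish"))        # stem
  layers <- c(layers, fused_mbconv(32, 16, 1, 3, 1))            # stage 1
  layers <- c(layers, fused_mbconv(16, 32, 4, 3, 2),            # stage 2
              fused_mbconv(32, 32, 4, 3, 1))
  layers <- c(layers, fused_mbconv(32, 48, 4, 3, 2),            # stage 3
              fused_mbconv(48, 48, 4, 3, 1))
  layers <- c(layers, mbconv(48, 96, 4, 3, 2))                  # stage 4
  for (i in 1:2) layers <- c(layers, mbconv(96, 96, 4, 3, 1))
  layers <- c(layers, mbconv(96, 112, 6, 3, 1))                 # stage 5
  for (i in 1:4) layers <- c(layers, mbconv(112, 112, 6, 3, 1))
  layers <- c(layers, mbconv(112, 192, 6, 3, 2))                # stage 6
  for (i in 1:7) layers <- c(layers, mbconv(192, 192, 6, 3, 1))
  c(layers, list(layer_conv(1, 1, 192, 1280, act = "swish")))   # top conv
}

# MobileNetV3 bottleneck; expansion conv is skipped when exp == cin
# (first block), SE reduction width follows the divisible-by-8 rule.
mnv3_bneck <- function(cin, exp, cout, k, stride, se, act) {
  residual <- stride == 1 && cin == cout
  layers <- list()
  if (residual) layers <- c(layers, list(layer_save()))
  if (exp != cin) layers <- c(layers, list(layer_conv(1, 1, cin, exp, act = act)))
  layers <- c(layers, list(layer_dwconv(k, stride, exp, act = act)))
  if (se) layers <- c(layers, list(layer_se(exp, depth8(exp * 0.25),
                                            act = "relu", gate = "hsigmoid")))
  layers <- c(layers, list(layer_conv(1, 1, exp, cout, act = NULL)))
  if (residual) layers <- c(layers, list(layer_add()))
  layers
}

mobilenetv3_small_layers <- function() {
  layers <- list(layer_conv(3, 2, 3, 16, act = "hswish"))       # stem
  cfg <- list(  # cin, exp, cout, k, stride, se, act
    list(16, 16, 16, 3, 2, TRUE, "relu"),
    list(16, 72, 24, 3, 2, FALSE, "relu"),
    list(24, 88, 24, 3, 1, FALSE, "relu"),
    list(24, 96, 40, 5, 2, TRUE, "hswish"),
    list(40, 240, 40, 5, 1, TRUE, "hswish"),
    list(40, 240, 40, 5, 1, TRUE, "hswish"),
    list(40, 120, 48, 5, 1, TRUE, "hswish"),
    list(48, 144, 48, 5, 1, TRUE, "hswish"),
    list(48, 288, 96, 5, 2, TRUE, "hswish"),
    list(96, 576, 96, 5, 1, TRUE, "hswish"),
    list(96, 576, 96, 5, 1, TRUE, "hswish"))
  for (b in cfg)
    layers <- c(layers, mnv3_bneck(b[[1]], b[[2]], b[[3]], b[[4]], b[[5]], b[[6]], b[[7]]))
  c(layers, list(layer_conv(1, 1, 96, 576, act = "hswish")))    # last conv
}

stub_layers <- function(channels = 64) {
  # three small convs, overall stride 16: a 224 input gives a 14x14 grid,
  # fine enough for quantitative saliency checks against structure masks.
  # Half the first-layer filters are mean-subtracted (zero-DC) edge/texture
  # detectors, half keep their color response: the random bank then covers
  # both cue families the synthetic classes are built from.
  list(layer_conv(7, 4, 3, 24, act = "relu", bn = FALSE, zero_dc = 0.5),
       layer_conv(5, 4, 24, channels, act = "relu", bn = FALSE, bias = TRUE),
       layer_conv(3, 1, channels, channels, act = "relu", bn = FALSE,
                  bias = TRUE))
}

# --- registry ---------------------------------------------------------------

.backbone_registry <- new.env(parent = emptyenv())

#' Register a backbone builder
#'
#' Adds a named builder to the backbone registry so it can be used as either
#' branch of the network. A builder is a function taking no arguments and
#' returning a list of layer specs; output channels are inferred from the
#' last conv layer.
#'
#' @param name Identifier used in configs and [build_backbone()].
#' @param builder Function returning a layer-spec list.
#' @export
register_backbone <- function(name, builder) {
  stopifnot(is.character(name), is.function(builder))
  assign(name, builder, envir = .backbone_registry)
  invisible(name)
}

backbone_builder <- function(name) {
  if (!exists(name, envir = .backbone_registry))
    stop("unknown backbone: ", name, call. = FALSE)
  get(name, envir = .backbone_registry)
}

#' Build a (frozen) convolutional backbone
#'
#' Instantiates a registered backbone layout with randomly initialized
#' weights. The canonical layouts `"effnetv2_b0"` and `"mobilenetv3_small"`
#' reproduce the published configurations with classification tops removed
#' (1280 and 576 output channels at a 7x7 grid for 224-pixel inputs).
#' `"stub"` is a two-conv network for fast tests and synthetic runs.
#'
#' @param name Registered backbone name.
#' @param input_size Input side length in pixels (default 224).
#' @param seed Integer seed for weight initialization.
#' @param frozen Logical; frozen backbones are never updated by training.
#' @return An object of class `bilight_backbone`.
#' @export
build_backbone <- function(name, input_size = 224L, seed = 1L, frozen = TRUE) {
  specs <- backbone_builder(name)()
  params <- with_seed(seed, function() lapply(specs, init_layer))
  convs <- Filter(function(s) s$type == "conv", specs)
  out_ch <- convs[[length(convs)]]$cout
  structure(list(name = name, input_size = as.integer(input_size),
                 output_channels = out_ch, layers = specs, params = params,
                 frozen = frozen),
            class = "bilight_backbone")
}

#' @export
print.bilight_backbone <- function(x, ...) {
  cat(sprintf("<bilight_backbone> %s: %d layers, %s -> %dx%dx%d, %s\n",
              x$name, length(x$layers), paste0(x$input_size, "px"),
              x$input_size %/% 32L, x$input_size %/% 32L, x$output_channels,
              if (x$frozen) "frozen" else "trainable"))
  invisible(x)
}

backbone_param_count <- function(backbone)
  sum(vapply(backbone$layers, layer_param_count, numeric(1)))

# Forward pass over one (H, W, C) image already in the backbone's native
# input scale. Frozen backbones run their norms in inference mode.
forward_backbone <- function(backbone, x) {
  stack <- list()
  for (i in seq_along(backbone$layers)) {
    s <- backbone$layers[[i]]; p <- backbone$params[[i]]
    if (s$type == "save") {
      stack[[length(stack) + 1L]] <- x
    } else if (s$type == "add") {
      x <- x + stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
    } else if (s$type == "conv") {
      x <- conv2d(x, p$w, bias = p$b, stride = s$stride)
      if (s$bn) x <- bn_infer(x, p$gamma, p$beta, p$mean, p$var)
      x <- apply_activation(x, s$act)
    } else if (s$type == "dwconv") {
      x <- dwconv2d(x, p$w, stride = s$stride)
      x <- bn_infer(x, p$gamma, p$beta, p$mean, p$var)
      x <- apply_activation(x, s$act)
    } else if (s$type == "se") {
      x <- se_block(x, p$w1, p$b1, p$w2, p$b2, act = s$act, gate = s$gate)
    }
  }
  x
}

#' Extract branch feature maps
#'
#' Runs a batch of RGB images through one frozen backbone and returns the
#' final convolutional activation grid. Callers always pass images in
#' \[0, 1\]; the branch's native input scaling (here \[-1, 1\]) is applied
#' internally.
#'
#' @param images A single (H, W, 3) array, an (N, H, W, 3) array, or a list
#'   of (H, W, 3) arrays, values in \[0, 1\].
#' @param backbone A `bilight_backbone`.
#' @return An (N, h, w, C) array with `C = backbone$output_channels` and
#'   `h = w = input_size / 32`.
#' @export
extract_features <- function(images, backbone) {
  stopifnot(inherits(backbone, "bilight_backbone"))
  imgs <- as_image_list(images)
  sz <- backbone$input_size
  for (im in imgs) {
    d <- dim(im)
    if (length(d) != 3L || d[1] != sz || d[2] != sz || d[3] != 3L)
      stop(sprintf("expected %dx%dx3 input images for backbone '%s', got %s",
                   sz, sz, backbone$name, paste(d, collapse = "x")),
           call. = FALSE)
  }
  maps <- lapply(imgs, function(im) forward_backbone(backbone, im * 2 - 1))
  dm <- dim(maps[[1]])
  out <- array(0, c(length(maps), dm))
  for (i in seq_along(maps)) out[i, , , ] <- maps[[i]]
  out
}

as_image_list <- function(images) {
  if (is.list(images)) return(images)
  d <- dim(images)
  if (length(d) == 3L) return(list(images))
  if (length(d) == 4L)
    return(lapply(seq_len(d[1]), function(i) array(images[i, , , ], d[-1])))
  stop("images must be an (H,W,3) array, an (N,H,W,3) array, or a list",
       call. = FALSE)
}

# canonical + stub layouts available out of the box
register_backbone("effnetv2_b0", effnetv2_b0_layers)
register_backbone("mobilenetv3_small", mobilenetv3_small_layers)
register_backbone("stub", function() stub_layers(64))
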