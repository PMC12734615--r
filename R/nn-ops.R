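# Low-level numeric primitives for the convolutional branches.
#
# Single images are (H, W, C) arrays in R's column-major layout; batches are
# (N, H, W, C). Convolutions use TensorFlow's "same" padding convention
# (total pad split floor/ceil between leading/trailing edges) so both
# canonical backbones map 224x224 inputs to a 7x7 grid at stride 32.

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)
relu6 <- function(x) pmin(pmax(x, 0), 6)
swish <- function(x) x * sigmoid(x)
hswish <- function(x) x * relu6(x + 3) / 6
hsigmoid <- function(x) relu6(x + 3) / 6
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

apply_activation <- function(x, act) {
  if (is.null(act)) return(x)
  switch(act,
    relu = relu(x), relu6 = relu6(x), swish = swish(x),
    hswish = hswish(x), sigmoid = sigmoid(x), hsigmoid = hsigmoid(x),
    linear = x,
    stop("unknown activation: ", act))
}

# "same" padding amounts for one spatial axis.
same_pad <- function(size, k, stride) {
  out <- ceiling(size / stride)
  total <- max((out - 1L) * stride + k - size, 0L)
  c(lead = floor(total / 2), trail = total - floor(total / 2), out = out)
}

pad_hw <- function(x, pt, pb, pl, pr) {
  if (pt == 0 && pb == 0 && pl == 0 && pr == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + pt + pb, d[2] + pl + pr, d[3]))
  out[(pt + 1):(pt + d[1]), (pl + 1):(pl + d[2]), ] <- x
  out
}

# Dense convolution via im2col + one matrix product. w: (k, k, cin, cout).
conv2d <- function(x, w, bias = NULL, stride = 1L) {
  d <- dim(x); k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  stopifnot(d[3] == cin)
  ph <- same_pad(d[1], k, stride); pw <- same_pad(d[2], k, stride)
  xp <- pad_hw(x, ph["lead"], ph["trail"], pw["lead"], pw["trail"])
  ho <- ph[["out"]]; wo <- pw[["out"]]
  ri <- seq.int(1L, by = stride, length.out = ho)
  ci <- seq.int(1L, by = stride, length.out = wo)
  cols <- matrix(0, ho * wo, k * k * cin)
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      sl <- xp[ri + di - 1L, ci + dj - 1L, , drop = FALSE]
      # column positions (di, dj) across all channels, matching the
      # (k, k, cin, cout) -> (k*k*cin, cout) reshape of w
      idx <- (seq_len(cin) - 1L) * (k * k) + (dj - 1L) * k + di
      cols[, idx] <- matrix(sl, ho * wo, cin)
    }
  }
  out <- cols %*% matrix(w, k * k * cin, cout)
  if (!is.null(bias)) out <- out + rep(bias, each = ho * wo)
  array(out, c(ho, wo, cout))
}

# Depthwise convolution. w: (k, k, c).
dwconv2d <- function(x, w, stride = 1L) {
  d <- dim(x); k <- dim(w)[1]; ch <- d[3]
  stopifnot(dim(w)[3] == ch)
  ph <- same_pad(d[1], k, stride); pw <- same_pad(d[2], k, stride)
  xp <- pad_hw(x, ph["lead"], ph["trail"], pw["lead"], pw["trail"])
  ho <- ph[["out"]]; wo <- pw[["out"]]
  ri <- seq.int(1L, by = stride, length.out = ho)
  ci <- seq.int(1L, by = stride, length.out = wo)
  out <- matrix(0, ho * wo, ch)
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      sl <- matrix(xp[ri + di - 1L, ci + dj - 1L, , drop = FALSE], ho * wo, ch)
      out <- out + sl * rep(w[di, dj, ], each = ho * wo)
    }
  }
  array(out, c(ho, wo, ch))
}

# Inference-mode batch norm over the channel axis of an (H, W, C) array.
bn_infer <- function(x, gamma, beta, mean, var, eps = 1e-3) {
  d <- dim(x)
  scale <- gamma / sqrt(var + eps)
  shift <- beta - mean * scale
  array(as.vector(x) * rep(scale, each = d[1] * d[2]) +
          rep(shift, each = d[1] * d[2]), d)
}

# Squeeze-and-excitation: channel-wise gating from the spatial mean.
# w1: (c, r), w2: (r, c); both carry biases.
se_block <- function(x, w1, b1, w2, b2, act = "swish", gate = "sigmoid") {
  d <- dim(x)
  s <- colMeans(matrix(x, d[1] * d[2], d[3]))
  a <- apply_activation(drop(s %*% w1) + b1, act)
  g <- apply_activation(drop(a %*% w2) + b2, gate)
  array(as.vector(x) * rep(g, each = d[1] * d[2]), d)
}

#' Bilinear image resize
#'
#' Resizes a 2-d matrix or (H, W, C) array with bilinear interpolation using
#' the half-pixel (align-corners = FALSE) convention, the same convention
#' used to bring 768x768 tiles down to the 224x224 network input and to
#' upsample Grad-CAM grids back to tile resolution.
#'
#' @param x Matrix or 3-d array.
#' @param out_h,out_w Target height and width in pixels.
#' @return Resized matrix or array with the channel count of `x`.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  is_mat <- is.matrix(x)
  if (is_mat) x <- array(x, c(dim(x), 1L))
  d <- dim(x)
  # half-pixel source coordinates, clamped to the grid
  src_r <- pmin(pmax((seq_len(out_h) - 0.5) * d[1] / out_h - 0.5, 0), d[1] - 1)
  src_c <- pmin(pmax((seq_len(out_w) - 0.5) * d[2] / out_w - 0.5, 0), d[2] - 1)
  r0 <- pmin(floor(src_r), d[1] - 1); r1 <- pmin(r0 + 1, d[1] - 1)
  c0 <- pmin(floor(src_c), d[2] - 1); c1 <- pmin(c0 + 1, d[2] - 1)
  fr <- src_r - r0; fc <- src_c - c0
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    pl <- x[, , ch]
    a <- pl[r0 + 1, c0 + 1, drop = FALSE] * (1 - fr) + pl[r1 + 1, c0 + 1, drop = FALSE] * fr
    b <- pl[r0 + 1, c1 + 1, drop = FALSE] * (1 - fr) + pl[r1 + 1, c1 + 1, drop = FALSE] * fr
    out[, , ch] <- a * rep(1 - fc, each = out_h) + b * rep(fc, each = out_h)
  }
  if (is_mat) out[, , 1] else out
}

# Deterministic local RNG: run fn under a seed without disturbing the
# caller's RNG stream.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

# Small integer hash used to derive per-tile / per-epoch seeds (< 2^31).
mix_seed <- function(...) {
  v <- c(...)
  h <- 0
  for (x in v) h <- (h * 131 + as.numeric(x) %% 1e9) %% 2147483647
  as.integer(h)
}
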