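# Branch descriptor: ECA channel re-weighting followed by triple pooling
# (GeM / GAP / GMP) and a dense GELU projection to a layer-normalized
# 128-d embedding. These are the documented single-map operations; the
# training loop runs an equivalent batched path (see train-core.R) and a
# test asserts the two agree.

check_feature_map <- function(F) {
  d <- dim(F)
  if (is.null(d) || length(d) != 3L)
    stop("feature map must be an (h, w, c) array", call. = FALSE)
  if (d[3] < 1L) stop("feature map needs at least one channel", call. = FALSE)
  d
}

#' Efficient channel attention (ECA) rescaling
#'
#' Re-weights the channels of a feature map by a sigmoid-gated 1-d
#' convolution over the vector of channel-wise spatial means. The gate lies
#' strictly in (0, 1) per channel, so ECA never changes the map's shape and
#' an all-zero kernel reduces to uniform 0.5 scaling.
#'
#' @param F An (h, w, c) feature map.
#' @param kernel Numeric vector of odd length: the 1-d convolution weights
#'   (no bias). Default length 5, the kernel size used throughout.
#' @return The rescaled feature map, same shape as `F`, with the gate vector
#'   attached as attribute `"gate"`.
#' @export
eca_rescale <- function(F, kernel = rep(0, 5)) {
  d <- check_feature_map(F)
  k <- length(kernel)
  if (k < 1L || k %% 2L == 0L) stop("ECA kernel length must be odd and >= 1",
                                    call. = FALSE)
  s <- colMeans(matrix(F, d[1] * d[2], d[3]))
  w <- sigmoid(conv1d_same(s, kernel))
  out <- array(as.vector(F) * rep(w, each = d[1] * d[2]), d)
  attr(out, "gate") <- w
  out
}

# zero-padded same-convolution of a vector with an odd-length kernel
conv1d_same <- function(s, kernel) {
  k <- length(kernel); pad <- (k - 1L) / 2L; n <- length(s)
  sp <- c(numeric(pad), s, numeric(pad))
  out <- numeric(n)
  for (j in seq_len(k)) out <- out + kernel[j] * sp[j:(j + n - 1L)]
  out
}

#' Generalized-mean (GeM) pooling
#'
#' Per-channel power mean `(mean(x^p))^(1/p)` over the spatial grid,
#' interpolating between average pooling (p = 1) and max pooling
#' (p -> Inf). Values are floored at 1e-6 before exponentiation.
#'
#' @param F An (h, w, c) feature map, elementwise nonnegative
#'   (post-activation).
#' @param p Pooling exponent, must be positive.
#' @return Numeric vector of length c.
#' @export
gem_pool <- function(F, p = 3) {
  d <- check_feature_map(F)
  if (!is.numeric(p) || length(p) != 1L || p <= 0)
    stop("GeM exponent p must be a positive scalar", call. = FALSE)
  x <- pmax(matrix(F, d[1] * d[2], d[3]), 1e-6)
  colMeans(x^p)^(1 / p)
}

#' Triple pooling descriptor
#'
#' Concatenates the three complementary poolings of a feature map in the
#' fixed order GeM, GAP, GMP (generalized mean, spatial average, spatial
#' maximum), giving a 3c-vector per branch.
#'
#' @inheritParams gem_pool
#' @return Numeric vector of length 3c, ordered `[GeM, GAP, GMP]`.
#' @export
pool_triplet <- function(F, p = 3) {
  d <- check_feature_map(F)
  m <- matrix(F, d[1] * d[2], d[3])
  c(gem_pool(F, p), colMeans(m), apply(m, 2, max))
}

#' Projection weights for a branch descriptor
#'
#' Random initialization (Glorot normal for the dense map, identity affine
#' for the layer norm) of the weights consumed by [project_descriptor()].
#'
#' @param in_dim Length of the pooled input vector (3c).
#' @param out_dim Latent dimension, default 128.
#' @param seed Integer seed.
#' @return List with `W` (in_dim x out_dim), `b`, `ln_gamma`, `ln_beta`.
#' @export
descriptor_weights <- function(in_dim, out_dim = 128L, seed = 1L) {
  with_seed(seed, function() list(
    W = matrix(stats::rnorm(in_dim * out_dim, 0, sqrt(2 / (in_dim + out_dim))),
               in_dim, out_dim),
    b = numeric(out_dim),
    ln_gamma = rep(1, out_dim),
    ln_beta = numeric(out_dim)))
}

#' Project pooled features to a normalized branch descriptor
#'
#' Affine map to the latent dimension, GELU activation, then layer
#' normalization (epsilon 1e-6) with a learned affine. Post-normalization
#' the descriptor has mean ~0 and unit variance across its dimensions
#' (before the affine rescale).
#'
#' @param pools Numeric vector of pooled features (length 3c).
#' @param weights Weight list as returned by [descriptor_weights()].
#' @return Numeric descriptor of length `ncol(weights$W)`.
#' @export
project_descriptor <- function(pools, weights) {
  if (!all(is.finite(pools))) stop("pooled features must be finite", call. = FALSE)
  if (length(pools) != nrow(weights$W))
    stop(sprintf("pooled vector length %d does not match projection rows %d",
                 length(pools), nrow(weights$W)), call. = FALSE)
  a <- gelu(drop(pools %*% weights$W) + weights$b)
  layernorm_vec(a, weights$ln_gamma, weights$ln_beta)
}

layernorm_vec <- function(a, gamma, beta, eps = 1e-6) {
  mu <- mean(a); v <- mean((a - mu)^2)
  (a - mu) / sqrt(v + eps) * gamma + beta
}
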