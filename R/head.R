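# Classification head (batch norm -> dropout -> softmax) and the
# label-smoothed cross-entropy loss.

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Head weights
#'
#' Initializes the classification head: batch-norm affine (gamma, beta) with
#' running statistics (mean, var), and the softmax classifier map.
#'
#' @param dim Fused descriptor dimension (default 128).
#' @param n_classes Number of classes C (default 5).
#' @param seed Integer seed.
#' @return List with `bn_gamma`, `bn_beta`, `bn_mean`, `bn_var`, `Wc`, `bc`.
#' @export
head_weights <- function(dim = 128L, n_classes = 5L, seed = 1L) {
  with_seed(seed, function() list(
    bn_gamma = rep(1, dim), bn_beta = numeric(dim),
    bn_mean = numeric(dim), bn_var = rep(1, dim),
    Wc = matrix(stats::rnorm(dim * n_classes, 0, sqrt(2 / (dim + n_classes))),
                dim, n_classes),
    bc = numeric(n_classes)))
}

#' Classify a fused descriptor
#'
#' `z = dropout(batchnorm(h))`, `y = softmax(Wc z + bc)`. In evaluation mode
#' (the default) dropout is the identity and batch norm uses its running
#' statistics, so the map is deterministic; in training mode batch norm uses
#' batch statistics and dropout masks activations at the given rate.
#'
#' @param h Fused descriptor: a vector of length d or an (N, d) matrix.
#' @param weights Head weights from [head_weights()].
#' @param training Logical; training-mode batch norm and dropout.
#' @param dropout Dropout rate in training mode (default 0.30).
#' @param bn_eps Batch-norm epsilon (default 1e-3).
#' @return Class-probability vector (or (N, C) matrix), rows on the simplex.
#' @export
classify <- function(h, weights, training = FALSE, dropout = 0.30,
                     bn_eps = 1e-3) {
  single <- is.null(dim(h))
  H <- if (single) matrix(h, 1) else h
  n <- nrow(H)
  if (training) {
    mu <- colMeans(H); v <- colMeans(H^2) - mu^2
  } else {
    mu <- weights$bn_mean; v <- weights$bn_var
  }
  z <- (H - rep(mu, each = n)) / rep(sqrt(v + bn_eps), each = n)
  z <- z * rep(weights$bn_gamma, each = n) + rep(weights$bn_beta, each = n)
  if (training && dropout > 0) {
    mask <- (stats::runif(length(z)) >= dropout) / (1 - dropout)
    z <- z * mask
  }
  probs <- softmax_rows(z %*% weights$Wc + rep(weights$bc, each = n))
  if (single) drop(probs) else probs
}

#' Label-smoothed categorical cross-entropy
#'
#' `loss = -sum_c y'_c log(p_c)` with smoothed targets
#' `y' = y (1 - epsilon) + epsilon / C`. With `epsilon = 0` this is the
#' standard cross-entropy; smoothing spreads a little target mass over all
#' classes to mitigate overconfident predictions. Probabilities are clamped
#' at 1e-12 before the log.
#'
#' @param y_true One-hot vector of length C, or an (N, C) one-hot matrix,
#'   or an integer vector of class indices (1-based) when `probs` is a
#'   matrix.
#' @param probs Predicted class probabilities matching `y_true`'s shape.
#' @param epsilon Smoothing parameter in `[0, 1)`.
#' @return Mean loss over the batch (scalar, nonnegative).
#' @export
smoothed_ce <- function(y_true, probs, epsilon = 0) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon >= 1)
    stop("label smoothing epsilon must lie in [0, 1)", call. = FALSE)
  P <- if (is.null(dim(probs))) matrix(probs, 1) else probs
  C <- ncol(P)
  Y <- if (is.null(dim(y_true)) && length(y_true) == C && is.null(dim(probs))) {
    matrix(y_true, 1)
  } else if (is.null(dim(y_true))) {
    onehot(as.integer(y_true), C)
  } else y_true
  Ys <- Y * (1 - epsilon) + epsilon / C
  -mean(rowSums(Ys * log(pmax(P, 1e-12))))
}

onehot <- function(idx, C) {
  Y <- matrix(0, length(idx), C)
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}
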