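# Cross-gated fusion of the two branch descriptors: a sigmoid gate computed
# from the concatenated descriptors mixes the branches per dimension, and a
# bilinear tanh interaction term captures non-linear cross-branch
# dependencies.

#' Cross-gated fusion weights
#'
#' Random (Glorot normal) initialization of the fusion block: the gate map
#' `Wg` (2d -> d, with bias), the two bilinear projections `WA`, `WB`
#' (d -> d, no bias), and the interaction output map `Wh` (d -> d, with
#' bias).
#'
#' @param dim Descriptor dimension d (default 128).
#' @param seed Integer seed.
#' @return List with `Wg`, `bg`, `WA`, `WB`, `Wh`, `bh`.
#' @export
fusion_weights <- function(dim = 128L, seed = 1L) {
  gl <- function(m, n) matrix(stats::rnorm(m * n, 0, sqrt(2 / (m + n))), m, n)
  with_seed(seed, function() list(
    Wg = gl(2L * dim, dim), bg = numeric(dim),
    WA = gl(dim, dim), WB = gl(dim, dim),
    Wh = gl(dim, dim), bh = numeric(dim)))
}

#' Compute the cross-branch gate
#'
#' `g = sigmoid(Wg [dA; dB] + bg)`: an elementwise gate in the open
#' interval (0, 1) that controls the per-dimension mix of the two branch
#' descriptors; its complement `1 - g` is applied to the other branch.
#'
#' @param dA,dB Branch descriptors (equal length d).
#' @param W Fusion weights from [fusion_weights()].
#' @return Gate vector of length d, values strictly in (0, 1).
#' @export
compute_gate <- function(dA, dB, W) {
  d <- ncol(W$Wg)
  if (length(dA) != d || length(dB) != d)
    stop(sprintf("descriptors must have length %d", d), call. = FALSE)
  sigmoid(drop(c(dA, dB) %*% W$Wg) + W$bg)
}

#' Fuse two branch descriptors
#'
#' `h = g * dA + (1 - g) * dB + Wh (tanh(WA dA) * tanh(WB dB)) + bh`: a
#' gated convex combination per dimension plus a bounded bilinear
#' interaction. With `Wh = 0` the result is a per-dimension convex
#' combination of the inputs; dropout is applied downstream in the head,
#' not here.
#'
#' @inheritParams compute_gate
#' @param g Gate vector as returned by [compute_gate()].
#' @return List with the fused descriptor `h`, the gate `g`, and its
#'   complement `g_complement`.
#' @export
fuse <- function(dA, dB, g, W) {
  stopifnot(length(dA) == length(dB), length(g) == length(dA))
  m <- tanh(drop(dA %*% W$WA)) * tanh(drop(dB %*% W$WB))
  h <- g * dA + (1 - g) * dB + drop(m %*% W$Wh) + W$bh
  list(h = h, g = g, g_complement = 1 - g)
}
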