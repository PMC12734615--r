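# Class-discriminative saliency. Channel weights are the spatial averages
# of the gradient of a pre-softmax class score with respect to a tapped
# convolutional activation grid; the saliency map is the rectified
# alpha-weighted sum of the activation maps. For the assembled model the
# gradient comes from the analytic backward pass (head_backward); arbitrary
# score functions must supply their own gradient.

#' Construct a differentiable score function
#'
#' Pairs a class-score function with its analytic gradient so it can be
#' tapped by [channel_weights()].
#'
#' @param value Function `(A, class)` returning the scalar pre-softmax
#'   score of `class` for activations `A` (h x w x K array).
#' @param grad Function `(A, class)` returning the gradient array
#'   `dscore/dA`, same shape as `A`.
#' @return Object of class `bilight_score`.
#' @export
differentiable_score <- function(value, grad) {
  stopifnot(is.function(value), is.function(grad))
  structure(list(value = value, grad = grad), class = "bilight_score")
}

#' Grad-CAM channel weights
#'
#' `alpha_k = (1/Z) * sum_ij d score / d A[i,j,k]` with `Z` the number of
#' spatial locations of the tapped layer: the gradient of the class score,
#' globally averaged over the spatial grid, one weight per activation map.
#'
#' @param score_fn A `bilight_score` (see [differentiable_score()]).
#' @param A Activations, (h, w, K) array.
#' @param class Class index passed through to the score.
#' @return Numeric vector of K channel weights.
#' @export
channel_weights <- function(score_fn, A, class = 1L) {
  if (!inherits(score_fn, "bilight_score"))
    stop("score function has no gradient; wrap it with differentiable_score()",
         call. = FALSE)
  d <- dim(A)
  stopifnot(length(d) == 3L)
  g <- score_fn$grad(A, class)
  stopifnot(identical(dim(g), d))
  colMeans(matrix(g, d[1] * d[2], d[3]))
}

#' Grad-CAM saliency map
#'
#' `L = ReLU(sum_k alpha_k A^k)`: the rectified weighted combination of the
#' activation maps, keeping only positive evidence for the class.
#'
#' @param alpha Channel weights (length K).
#' @param A Activations, (h, w, K) array.
#' @return Nonnegative (h, w) matrix of class `bilight_saliency`, with
#'   attributes `alpha` and `Z`.
#' @export
saliency <- function(alpha, A) {
  d <- dim(A)
  if (length(alpha) != d[3])
    stop("alpha length must equal the number of activation maps", call. = FALSE)
  L <- matrix(matrix(A, d[1] * d[2], d[3]) %*% alpha, d[1], d[2])
  L <- pmax(L, 0)
  structure(L, class = c("bilight_saliency", "matrix"),
            alpha = alpha, Z = d[1] * d[2])
}

#' Grad-CAM for an assembled model
#'
#' Taps the final convolutional activation grid of one branch (the layer
#' feeding the descriptor), computes the gradient of the pre-softmax class
#' score through the fusion head by the analytic backward pass, and returns
#' the rectified saliency map at the tapped layer's resolution.
#'
#' @param model A `bilight_model`.
#' @param tile An (H, W, 3) RGB tile in [0, 1], or a list
#'   `list(FA = , FB = )` of precomputed (1, h, w, C) feature maps.
#' @param class Class index (1-based) or label; default the predicted
#'   class.
#' @param branch `"a"` or `"b"`: which branch's last convolutional layer to
#'   tap; `"both"` sums the two branches' rectified maps (each bilinearly
#'   resampled to the finer grid), giving the model's total positive class
#'   evidence.
#' @return A `bilight_saliency` matrix with attributes `alpha`, `Z`,
#'   `class_index`, `layer_id`.
#' @export
gradcam <- function(model, tile, class = NULL, branch = c("a", "b", "both")) {
  branch <- match.arg(branch)
  if (branch == "both") {
    La <- gradcam(model, tile, class = class, branch = "a")
    Lb <- gradcam(model, tile, class = class, branch = "b")
    d <- pmax(dim(La), dim(Lb))
    L <- bilinear_resize(unclass(La), d[1], d[2]) +
      bilinear_resize(unclass(Lb), d[1], d[2])
    return(structure(L, class = c("bilight_saliency", "matrix"),
                     alpha = c(attr(La, "alpha"), attr(Lb, "alpha")),
                     Z = d[1] * d[2],
                     class_index = attr(La, "class_index"),
                     layer_id = "both_branches/final_conv"))
  }
  stopifnot(inherits(model, "bilight_model"))
  if (is.list(tile) && !is.null(tile$FA)) {
    FA <- tile$FA; FB <- tile$FB
  } else {
    FA <- extract_features(tile, model$backbone_a)
    FB <- extract_features(tile, model$backbone_b)
  }
  fw <- head_forward(model$par, FA, FB, training = FALSE)
  ci <- if (is.null(class)) which.max(fw$probs[1, ])
        else if (is.numeric(class)) as.integer(class)
        else match(class, model$classes)
  stopifnot(!is.na(ci), ci >= 1, ci <= length(model$classes))
  dLOG <- matrix(0, 1, length(model$classes)); dLOG[1, ci] <- 1
  bw <- head_backward(model$par, fw, dLOG)
  dF <- if (branch == "a") bw$dFA else bw$dFB
  A3 <- array(if (branch == "a") FA[1, , , ] else FB[1, , , ], dim(dF)[-1])
  g3 <- array(dF[1, , , ], dim(dF)[-1])
  d <- dim(A3)
  alpha <- colMeans(matrix(g3, d[1] * d[2], d[3]))
  out <- saliency(alpha, A3)
  attr(out, "class_index") <- ci
  attr(out, "layer_id") <- paste0("backbone_", branch, "/final_conv")
  out
}

# piecewise-linear jet-style colormap on [0, 1]
jet_color <- function(v) {
  r <- pmin(pmax(1.5 - abs(4 * v - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * v - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * v - 1), 0), 1)
  cbind(r, g, b)
}

#' Render a saliency overlay
#'
#' Min-max normalizes the saliency map (an all-zero map stays zero),
#' bilinearly upsamples it to the tile's resolution, maps it through a
#' fixed blue-to-red colormap and alpha-blends it over the tile.
#' Deterministic.
#'
#' @param tile (H, W, 3) RGB tile in [0, 1].
#' @param L Saliency map (any nonnegative matrix).
#' @param alpha Blend weight of the heatmap (default 0.4).
#' @return (H, W, 3) RGB overlay in [0, 1].
#' @export
render_overlay <- function(tile, L, alpha = 0.4) {
  stopifnot(all(L >= 0))
  d <- dim(tile)
  Lm <- as.matrix(L)
  rng <- range(Lm)
  if (rng[2] > rng[1]) Lm <- (Lm - rng[1]) / (rng[2] - rng[1])
  up <- bilinear_resize(Lm, d[1], d[2])
  heat <- array(jet_color(as.vector(up)), c(d[1], d[2], 3))
  (1 - alpha) * tile + alpha * heat
}
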