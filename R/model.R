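# Model assembly and the parameter audit.
#
# A bilight_model bundles two frozen backbones with the trainable part: one
# ECA + GeM + projection descriptor per branch, the cross-gated fusion
# block, and the batch-normalized softmax head. Trainable parameters are
# kept as a flat named list; each array carries a "trainable" attribute the
# audit relies on.

#' Canonical class labels
#'
#' The five diagnostic categories in the lexicographic class-per-folder
#' order of the LC25000 layout.
#' @return Character vector of length 5.
#' @export
bilight_classes <- function()
  c("colon_aca", "colon_n", "lung_aca", "lung_n", "lung_scc")

tr <- function(x, trainable = TRUE) { attr(x, "trainable") <- trainable; x }

# Flat trainable-parameter list for given branch channel counts.
init_head_params <- function(cA, cB, dim = 128L, n_classes = 5L,
                             eca_k = 5L, gem_p_init = 3, seed = 1L) {
  gl <- function(m, n) matrix(stats::rnorm(m * n, 0, sqrt(2 / (m + n))), m, n)
  with_seed(seed, function() list(
    a_eca = tr(stats::rnorm(eca_k, 0, 0.3)),
    a_gem_p = tr(gem_p_init),
    a_W1 = tr(gl(3L * cA, dim)), a_b1 = tr(numeric(dim)),
    a_ln_g = tr(rep(1, dim)), a_ln_b = tr(numeric(dim)),
    b_eca = tr(stats::rnorm(eca_k, 0, 0.3)),
    b_gem_p = tr(gem_p_init),
    b_W1 = tr(gl(3L * cB, dim)), b_b1 = tr(numeric(dim)),
    b_ln_g = tr(rep(1, dim)), b_ln_b = tr(numeric(dim)),
    Wg = tr(gl(2L * dim, dim)), bg = tr(numeric(dim)),
    WA = tr(gl(dim, dim)), WB = tr(gl(dim, dim)),
    # interaction output and classifier start at zero: the bilinear path
    # and the class scores are learned from scratch, so early-training
    # saliency reflects learned evidence only
    Wh = tr(matrix(0, dim, dim)), bh = tr(numeric(dim)),
    bn_g = tr(rep(1, dim)), bn_b = tr(numeric(dim)),
    bn_mean = tr(numeric(dim), FALSE), bn_var = tr(rep(1, dim), FALSE),
    Wc = tr(matrix(0, dim, n_classes)), bc = tr(numeric(n_classes))))
}

head_component_of <- local({
  map <- c(a_eca = "descriptor_a", a_gem_p = "descriptor_a",
           a_W1 = "descriptor_a", a_b1 = "descriptor_a",
           a_ln_g = "descriptor_a", a_ln_b = "descriptor_a",
           b_eca = "descriptor_b", b_gem_p = "descriptor_b",
           b_W1 = "descriptor_b", b_b1 = "descriptor_b",
           b_ln_g = "descriptor_b", b_ln_b = "descriptor_b",
           Wg = "fusion", bg = "fusion", WA = "fusion", WB = "fusion",
           Wh = "fusion", bh = "fusion",
           bn_g = "head", bn_b = "head", bn_mean = "head", bn_var = "head",
           Wc = "head", bc = "head")
  function(name) unname(map[name])
})

#' Assemble the dual-branch network
#'
#' Builds both backbones (frozen) and initializes the trainable descriptor,
#' fusion, and head parameters for their channel counts.
#'
#' @param backbone_a,backbone_b Registered backbone names; defaults are the
#'   canonical `"effnetv2_b0"` and `"mobilenetv3_small"` layouts.
#' @param input_size Input side length in pixels (default 224).
#' @param classes Character vector of class labels.
#' @param dim Latent descriptor dimension (default 128).
#' @param eca_k ECA 1-d kernel size (odd, default 5).
#' @param gem_p_init Initial GeM exponent (default 3; learnable per branch).
#' @param dropout Head dropout rate in training mode (default 0.30).
#' @param label_smoothing Cross-entropy smoothing epsilon (default 0).
#' @param seed Integer seed for all weight initialization.
#' @return An object of class `bilight_model`.
#' @export
bilight_model <- function(backbone_a = "effnetv2_b0",
                          backbone_b = "mobilenetv3_small",
                          input_size = 224L, classes = bilight_classes(),
                          dim = 128L, eca_k = 5L, gem_p_init = 3,
                          dropout = 0.30, label_smoothing = 0, seed = 1L) {
  ba <- build_backbone(backbone_a, input_size, seed = mix_seed(seed, 1))
  bb <- build_backbone(backbone_b, input_size, seed = mix_seed(seed, 2))
  par <- init_head_params(ba$output_channels, bb$output_channels, dim,
                          length(classes), eca_k, gem_p_init,
                          seed = mix_seed(seed, 3))
  structure(list(backbone_a = ba, backbone_b = bb, par = par,
                 classes = classes, dim = dim, dropout = dropout,
                 label_smoothing = label_smoothing,
                 input_size = as.integer(input_size)),
            class = "bilight_model")
}

#' @export
print.bilight_model <- function(x, ...) {
  aud <- audit_parameters(x)
  cat(sprintf("<bilight_model> %s + %s -> %d classes (%s)\n",
              x$backbone_a$name, x$backbone_b$name, length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  parameters: %s total (%s trainable, %s non-trainable), %.2f MiB\n",
              format(aud$total, big.mark = ","),
              format(aud$trainable, big.mark = ","),
              format(aud$non_trainable, big.mark = ","), aud$size_mib))
  invisible(x)
}

#' Parameter audit
#'
#' Counts every weight, bias, normalization scale/shift, and running
#' statistic in the assembled model, classified by trainable flag and by
#' component. The float32 model size follows as `total * 4 / 2^20` MiB.
#'
#' @param model A `bilight_model`.
#' @return An object of class `bilight_audit`: list with `total`,
#'   `trainable`, `non_trainable`, `by_component`, `size_mib`.
#' @export
audit_parameters <- function(model) {
  stopifnot(inherits(model, "bilight_model"))
  by_comp <- c(backbone_a = backbone_param_count(model$backbone_a),
               backbone_b = backbone_param_count(model$backbone_b),
               descriptor_a = 0, descriptor_b = 0, fusion = 0, head = 0)
  trainable <- 0
  if (!model$backbone_a$frozen) trainable <- trainable + by_comp[["backbone_a"]]
  if (!model$backbone_b$frozen) trainable <- trainable + by_comp[["backbone_b"]]
  for (nm in names(model$par)) {
    n <- length(model$par[[nm]])
    comp <- head_component_of(nm)
    by_comp[comp] <- by_comp[comp] + n
    if (isTRUE(attr(model$par[[nm]], "trainable"))) trainable <- trainable + n
  }
  total <- sum(by_comp)
  structure(list(total = total, trainable = trainable,
                 non_trainable = total - trainable,
                 by_component = by_comp,
                 size_mib = total * 4 / 2^20),
            class = "bilight_audit")
}

#' @export
print.bilight_audit <- function(x, ...) {
  cat("Parameter audit\n")
  for (nm in names(x$by_component))
    cat(sprintf("  %-14s %12s\n", nm,
                format(x$by_component[[nm]], big.mark = ",")))
  cat(sprintf("  %-14s %12s\n", "total", format(x$total, big.mark = ",")))
  cat(sprintf("  trainable %s / non-trainable %s; float32 size %.2f MiB\n",
              format(x$trainable, big.mark = ","),
              format(x$non_trainable, big.mark = ","), x$size_mib))
  invisible(x)
}

#' @export
as.list.bilight_audit <- function(x, ...) unclass(x)
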