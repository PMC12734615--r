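# Grad-CAM: channel weights against analytic and finite-difference
# oracles, saliency composition, and overlay rendering.

test_that("channel weights match the closed form of a linear score and a
           finite-difference oracle", {
  set.seed(1)
  A <- array(stats::rnorm(4 * 4 * 3), c(4, 4, 3))
  wk <- c(2, -1, 0.5)
  Z <- 16
  score <- differentiable_score(
    value = function(A, class) sum(wk * apply(A, 3, mean)),
    grad = function(A, class) {
      g <- array(0, dim(A))
      for (k in 1:3) g[, , k] <- wk[k] / Z
      g
    })
  alpha <- channel_weights(score, A)
  expect_equal(alpha, wk / Z, tolerance = 1e-12)
  # independent finite-difference oracle computed here in the test
  h <- 1e-5
  alpha_fd <- numeric(3)
  for (k in 1:3) {
    gsum <- 0
    for (i in 1:4) for (j in 1:4) {
      Ap <- A; Ap[i, j, k] <- Ap[i, j, k] + h
      Am <- A; Am[i, j, k] <- Am[i, j, k] - h
      gsum <- gsum + (score$value(Ap, 1) - score$value(Am, 1)) / (2 * h)
    }
    alpha_fd[k] <- gsum / Z
  }
  expect_equal(alpha, alpha_fd, tolerance = 1e-4)
  # linear map: doubling the activations leaves alpha unchanged
  expect_equal(channel_weights(score, 2 * A), alpha)
})

test_that("a constant score yields zero weights and plain functions are
           rejected", {
  A <- array(1, c(3, 3, 2))
  const <- differentiable_score(function(A, class) 5,
                                function(A, class) array(0, dim(A)))
  expect_equal(channel_weights(const, A), c(0, 0))
  expect_error(channel_weights(function(A) sum(A), A), "gradient")
})

test_that("saliency is the rectified weighted map combination", {
  set.seed(2)
  A <- array(stats::rnorm(5 * 5), c(5, 5, 1))
  expect_equal(unclass(saliency(1, A))[, ], pmax(A[, , 1], 0),
               ignore_attr = TRUE)
  Apos <- abs(A)
  expect_true(all(saliency(-1, Apos) == 0))
  A2 <- array(c(rep(1, 9), rep(2, 9)), c(3, 3, 2))
  expect_true(all(abs(saliency(c(0.5, 0.25), A2) - 1) < 1e-12))
  expect_error(saliency(c(1, 2), A), "number of activation maps")
})

test_that("saliency is scale-covariant in the weights before
           normalization", {
  set.seed(3)
  A <- array(stats::rnorm(4 * 4 * 6), c(4, 4, 6))
  alpha <- stats::rnorm(6)
  L1 <- saliency(alpha, A)
  for (lam in c(0.5, 3))
    expect_equal(unclass(saliency(lam * alpha, A)), lam * unclass(L1),
                 ignore_attr = TRUE)
})

test_that("model-level Grad-CAM matches finite differences through the
           fused head", {
  m <- bilight_model("stub", "stub", classes = bilight_classes(), seed = 5)
  set.seed(6)
  cA <- m$backbone_a$output_channels
  cB <- m$backbone_b$output_channels
  FA <- array(abs(stats::rnorm(1 * 7 * 7 * cA)), c(1, 7, 7, cA))
  FB <- array(abs(stats::rnorm(1 * 7 * 7 * cB)), c(1, 7, 7, cB))
  L <- gradcam(m, list(FA = FA, FB = FB), class = 2, branch = "a")
  alpha <- attr(L, "alpha")
  expect_length(alpha, cA)
  expect_true(all(L >= 0))
  score_of <- function(FAx)
    bilight:::head_forward(m$par, FAx, FB, training = FALSE)$logits[1, 2]
  h <- 1e-5
  for (k in c(1, 5, 12)) {          # spot-check channels against the oracle
    gsum <- 0
    for (i in 1:7) for (j in 1:7) {
      Ap <- FA; Ap[1, i, j, k] <- Ap[1, i, j, k] + h
      Am <- FA; Am[1, i, j, k] <- Am[1, i, j, k] - h
      gsum <- gsum + (score_of(Ap) - score_of(Am)) / (2 * h)
    }
    expect_equal(alpha[k], gsum / 49, tolerance = 1e-4)
  }
})

test_that("overlay rendering preserves size, blends an all-zero map as the
           plain tile, and keeps the peak in place", {
  set.seed(7)
  tile <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  L0 <- matrix(0, 8, 8)
  ov <- render_overlay(tile, L0, alpha = 0.4)
  expect_equal(dim(ov), dim(tile))
  zero_heat <- bilight:::jet_color(0)
  for (ch in 1:3)
    expect_equal(ov[, , ch], 0.6 * tile[, , ch] + 0.4 * zero_heat[ch])
  # single-peak map: upsampled argmax lands within one upsampling cell
  L <- matrix(0, 8, 8); L[3, 6] <- 1
  up <- bilinear_resize(L, 32, 32)
  peak <- which(up == max(up), arr.ind = TRUE)[1, ]
  expect_lt(abs(peak[1] - (3 - 0.5) * 4), 4 + 1e-9)
  expect_lt(abs(peak[2] - (6 - 0.5) * 4), 4 + 1e-9)
  expect_error(render_overlay(tile, matrix(-1, 4, 4)), "L >= 0")
})
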