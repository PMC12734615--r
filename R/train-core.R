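# Batched forward and backward passes through the trainable part of the
# network: per-branch ECA -> (GeM, GAP, GMP) -> dense GELU -> layer norm,
# cross-gated fusion, batch-normalized dropout softmax head. Gradients are
# derived by hand; the backward pass also returns gradients with respect to
# the branch feature maps, which is what Grad-CAM taps.
#
# Batch layout: feature maps are (N, H, W, C) arrays, flattened to
# (N, H*W*C) matrices whose columns hold channel-contiguous blocks of H*W
# spatial positions.

chan_mean <- function(M, N, HW, C)
  colMeans(aperm(array(M, c(N, HW, C)), c(2, 1, 3)))
chan_sum <- function(M, N, HW, C)
  colSums(aperm(array(M, c(N, HW, C)), c(2, 1, 3)))
expand_chan <- function(W, HW) W[, rep(seq_len(ncol(W)), each = HW), drop = FALSE]

# batched zero-padded same 1-d convolution along the channel axis
conv1d_batch <- function(S, kern) {
  k <- length(kern); pad <- (k - 1L) / 2L
  N <- nrow(S); C <- ncol(S)
  Sp <- cbind(matrix(0, N, pad), S, matrix(0, N, pad))
  out <- matrix(0, N, C)
  for (j in seq_len(k)) out <- out + kern[j] * Sp[, j:(j + C - 1L), drop = FALSE]
  out
}

GEM_FLOOR <- 1e-6
LN_EPS <- 1e-6
BN_EPS <- 1e-3

# One branch: feature maps -> normalized descriptors, with cache.
branch_forward <- function(F4, par, prefix) {
  g <- function(nm) par[[paste0(prefix, "_", nm)]]
  d <- dim(F4); N <- d[1]; HW <- d[2] * d[3]; C <- d[4]
  M <- matrix(F4, N, HW * C)
  S <- chan_mean(M, N, HW, C)
  Tt <- conv1d_batch(S, g("eca"))
  W8 <- sigmoid(Tt)
  Wfull <- expand_chan(W8, HW)
  Mt <- M * Wfull
  p <- as.numeric(g("gem_p"))
  X <- pmax(Mt, GEM_FLOOR)
  XP <- X^p
  Mp <- chan_mean(XP, N, HW, C)
  gem <- Mp^(1 / p)
  gap <- chan_mean(Mt, N, HW, C)
  arrt <- array(Mt, c(N, HW, C))
  gmp <- matrix(-Inf, N, C)
  for (j in seq_len(HW)) gmp <- pmax(gmp, matrix(arrt[, j, ], N, C))
  U <- cbind(gem, gap, gmp)
  Z1 <- U %*% g("W1") + rep(g("b1"), each = N)
  A <- gelu(Z1)
  mu <- rowMeans(A)
  V <- rowMeans((A - mu)^2)
  istd <- 1 / sqrt(V + LN_EPS)
  Xhat <- (A - mu) * istd
  D <- Xhat * rep(g("ln_g"), each = N) + rep(g("ln_b"), each = N)
  list(D = D, M = M, S = S, W8 = W8, Wfull = Wfull, Mt = Mt, X = X, XP = XP,
       Mp = Mp, gem = gem, gmp = gmp, U = U, Z1 = Z1, Xhat = Xhat,
       istd = istd, p = p, dims = d)
}

branch_backward <- function(dD, cache, par, prefix) {
  g <- function(nm) par[[paste0(prefix, "_", nm)]]
  d <- cache$dims; N <- d[1]; HW <- d[2] * d[3]; C <- d[4]
  k <- length(g("eca")); pad <- (k - 1L) / 2L
  # layer norm
  dln_g <- colSums(dD * cache$Xhat); dln_b <- colSums(dD)
  dXhat <- dD * rep(g("ln_g"), each = N)
  dA <- cache$istd *
    (dXhat - rowMeans(dXhat) - cache$Xhat * rowMeans(dXhat * cache$Xhat))
  dZ1 <- dA * gelu_grad(cache$Z1)
  dW1 <- crossprod(cache$U, dZ1); db1 <- colSums(dZ1)
  dU <- tcrossprod(dZ1, g("W1"))
  dgem <- dU[, seq_len(C), drop = FALSE]
  dgap <- dU[, C + seq_len(C), drop = FALSE]
  dgmp <- dU[, 2L * C + seq_len(C), drop = FALSE]
  # GMP: gradient to the (possibly tied) spatial maxima
  gmp_full <- expand_chan(cache$gmp, HW)
  mask <- (cache$Mt == gmp_full) * 1
  cnt <- chan_sum(mask, N, HW, C)
  dMt <- mask * expand_chan(dgmp / cnt, HW)
  # GAP
  dMt <- dMt + expand_chan(dgap / HW, HW)
  # GeM (floored at GEM_FLOOR before the power)
  p <- cache$p
  coef <- dgem * cache$Mp^(1 / p - 1) / HW
  dX <- expand_chan(coef, HW) * cache$X^(p - 1)
  dMt <- dMt + dX * (cache$Mt > GEM_FLOOR)
  Mlog <- chan_mean(cache$XP * log(cache$X), N, HW, C)
  dy_dp <- cache$gem * (-log(cache$Mp) / p^2 + Mlog / (p * cache$Mp))
  dp <- sum(dgem * dy_dp)
  # ECA
  dM <- dMt * cache$Wfull
  dw <- chan_sum(dMt * cache$M, N, HW, C)
  dT <- dw * cache$W8 * (1 - cache$W8)
  Tp <- cbind(matrix(0, N, pad), dT, matrix(0, N, pad))
  dS <- matrix(0, N, C)
  kern <- g("eca")
  for (j in seq_len(k)) dS <- dS + kern[j] * Tp[, (k - j + 1L):(k - j + C), drop = FALSE]
  Sp <- cbind(matrix(0, N, pad), cache$S, matrix(0, N, pad))
  dkern <- vapply(seq_len(k),
                  function(j) sum(Sp[, j:(j + C - 1L), drop = FALSE] * dT),
                  numeric(1))
  dM <- dM + expand_chan(dS / HW, HW)
  grads <- list(eca = dkern, gem_p = dp, W1 = dW1, b1 = db1,
                ln_g = dln_g, ln_b = dln_b)
  names(grads) <- paste0(prefix, "_", names(grads))
  grads$dF <- array(dM, d)
  grads
}

# Full trainable-head forward. `labels` (1-based ints) are optional; when
# given, the smoothed cross-entropy loss is computed.
head_forward <- function(par, FA, FB, training = FALSE, dropout = 0.30,
                         label_smoothing = 0, labels = NULL) {
  ca <- branch_forward(FA, par, "a")
  cb <- branch_forward(FB, par, "b")
  DA <- ca$D; DB <- cb$D; N <- nrow(DA)
  CC <- cbind(DA, DB)
  PRE <- CC %*% par$Wg + rep(par$bg, each = N)
  G <- sigmoid(PRE)
  TA <- tanh(DA %*% par$WA); TB <- tanh(DB %*% par$WB)
  Mm <- TA * TB
  H <- G * DA + (1 - G) * DB + Mm %*% par$Wh + rep(par$bh, each = N)
  if (training) {
    mub <- colMeans(H); varb <- colMeans(H^2) - mub^2
  } else {
    mub <- par$bn_mean; varb <- par$bn_var
  }
  istdb <- 1 / sqrt(varb + BN_EPS)
  Xh <- (H - rep(mub, each = N)) * rep(istdb, each = N)
  BNout <- Xh * rep(par$bn_g, each = N) + rep(par$bn_b, each = N)
  mask <- NULL
  Z <- BNout
  if (training && dropout > 0) {
    mask <- matrix((stats::runif(length(Z)) >= dropout) / (1 - dropout),
                   nrow(Z), ncol(Z))
    Z <- Z * mask
  }
  LOG <- Z %*% par$Wc + rep(par$bc, each = N)
  P <- softmax_rows(LOG)
  loss <- NULL
  if (!is.null(labels))
    loss <- smoothed_ce(labels, P, label_smoothing)
  list(probs = P, logits = LOG, loss = loss,
       cache = list(ca = ca, cb = cb, DA = DA, DB = DB, CC = CC, G = G,
                    TA = TA, TB = TB, Mm = Mm, H = H, Xh = Xh, Z = Z,
                    mask = mask, istdb = istdb, mub = mub, varb = varb,
                    training = training, N = N))
}

# Backward from a gradient on the logits. For training with mean smoothed
# CE use dLOG = (P - Y') / N; for Grad-CAM use a one-hot row.
head_backward <- function(par, fw, dLOG) {
  cc <- fw$cache; N <- cc$N
  dWc <- crossprod(cc$Z, dLOG); dbc <- colSums(dLOG)
  dZ <- tcrossprod(dLOG, par$Wc)
  if (!is.null(cc$mask)) dZ <- dZ * cc$mask
  dbn_g <- colSums(dZ * cc$Xh); dbn_b <- colSums(dZ)
  dXh <- dZ * rep(par$bn_g, each = N)
  if (cc$training) {
    dH <- rep(cc$istdb, each = N) *
      (dXh - rep(colMeans(dXh), each = N) -
         cc$Xh * rep(colMeans(dXh * cc$Xh), each = N))
  } else {
    dH <- dXh * rep(cc$istdb, each = N)
  }
  # fusion
  dG <- dH * (cc$DA - cc$DB)
  dMm <- tcrossprod(dH, par$Wh)
  dWh <- crossprod(cc$Mm, dH); dbh <- colSums(dH)
  dUA <- dMm * cc$TB * (1 - cc$TA^2)
  dUB <- dMm * cc$TA * (1 - cc$TB^2)
  dWA <- crossprod(cc$DA, dUA); dWB <- crossprod(cc$DB, dUB)
  dPRE <- dG * cc$G * (1 - cc$G)
  dWg <- crossprod(cc$CC, dPRE); dbg <- colSums(dPRE)
  dCCg <- tcrossprod(dPRE, par$Wg)
  dim_d <- ncol(cc$DA)
  dDA <- dH * cc$G + tcrossprod(dUA, par$WA) + dCCg[, seq_len(dim_d), drop = FALSE]
  dDB <- dH * (1 - cc$G) + tcrossprod(dUB, par$WB) +
    dCCg[, dim_d + seq_len(dim_d), drop = FALSE]
  ga <- branch_backward(dDA, cc$ca, par, "a")
  gb <- branch_backward(dDB, cc$cb, par, "b")
  dFA <- ga$dF; ga$dF <- NULL
  dFB <- gb$dF; gb$dF <- NULL
  grads <- c(ga, gb,
             list(Wg = dWg, bg = dbg, WA = dWA, WB = dWB, Wh = dWh, bh = dbh,
                  bn_g = dbn_g, bn_b = dbn_b, Wc = dWc, bc = dbc))
  list(grads = grads, dFA = dFA, dFB = dFB)
}

# Running-statistic update for the head batch norm (momentum 0.99, biased
# batch variance), applied by the training loop after each step.
bn_update_running <- function(par, fw, momentum = 0.99) {
  cc <- fw$cache
  par$bn_mean <- tr(momentum * par$bn_mean + (1 - momentum) * cc$mub, FALSE)
  par$bn_var <- tr(momentum * par$bn_var + (1 - momentum) * cc$varb, FALSE)
  par
}

# Precise batch-norm calibration: replace the exponentially averaged
# running statistics with the exact first/second moments of the fused
# representation over a reference set (training features, dropout off).
# Momentum-tracked statistics lag the weights on short runs; this pass
# makes evaluation-mode inference consistent with the current weights.
bn_recalibrate <- function(par, FA, FB, batch_size = 64L) {
  n <- dim(FA)[1]
  s1 <- 0; s2 <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fw <- head_forward(par, FA[idx, , , , drop = FALSE],
                       FB[idx, , , , drop = FALSE],
                       training = TRUE, dropout = 0)
    H <- fw$cache$H
    s1 <- s1 + colSums(H); s2 <- s2 + colSums(H^2)
  }
  mu <- s1 / n
  par$bn_mean <- tr(mu, FALSE)
  par$bn_var <- tr(pmax(s2 / n - mu^2, 0), FALSE)
  par
}
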