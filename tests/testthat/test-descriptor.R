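# ECA rescaling, GeM/triple pooling, and the descriptor projection.

test_that("ECA with an all-zero kernel halves the map and preserves shape", {
  F <- rand_fmap(5, 5, 4, seed = 2)
  out <- eca_rescale(F, kernel = rep(0, 5))
  expect_identical(dim(out), dim(F))
  expect_equal(as.vector(out), as.vector(0.5 * F))
  expect_equal(attr(out, "gate"), rep(0.5, 4))
})

test_that("ECA gate follows sigmoid of the kernel response exactly", {
  # single channel, centered kernel weight gamma: w = sigmoid(gamma * mean(F))
  F <- array(2, c(3, 3, 1))
  for (gamma in c(-1, 1)) {
    out <- eca_rescale(F, kernel = c(0, 0, gamma, 0, 0))
    expect_equal(attr(out, "gate"), 1 / (1 + exp(-2 * gamma)),
                 tolerance = 1e-12)
  }
  expect_equal(attr(eca_rescale(F, c(0, 0, 1, 0, 0)), "gate"), 0.8808,
               tolerance = 1e-4)
  expect_equal(attr(eca_rescale(F, c(0, 0, -1, 0, 0)), "gate"), 0.1192,
               tolerance = 1e-4)
})

test_that("ECA rejects malformed inputs", {
  F <- rand_fmap()
  expect_error(eca_rescale(F, kernel = rep(0, 4)), "odd")
  expect_error(eca_rescale(matrix(1, 3, 3)), "array")
})

test_that("GeM matches its closed forms and limit cases", {
  F <- array(c(1, 2, 3, 4), c(2, 2, 1))
  expect_equal(gem_pool(F, p = 1), mean(1:4))
  expect_equal(gem_pool(F, p = 2), sqrt((1 + 4 + 9 + 16) / 4))
  expect_equal(gem_pool(F, p = 2), 2.7386, tolerance = 1e-4)
  expect_equal(gem_pool(F, p = 3), ((1 + 8 + 27 + 64) / 4)^(1 / 3))
  expect_equal(gem_pool(F, p = 3), 2.9240, tolerance = 1e-4)
  Fc <- array(0.7, c(3, 5, 2))
  for (p in c(1, 2, 3, 7)) expect_equal(gem_pool(Fc, p), rep(0.7, 2))
  expect_error(gem_pool(F, p = 0), "positive")
  expect_error(gem_pool(F, p = -2), "positive")
})

test_that("GeM is positively homogeneous in the map", {
  F <- rand_fmap(4, 4, 3, seed = 5)
  for (lam in c(0.5, 2, 10))
    expect_equal(gem_pool(F * lam, p = 3), lam * gem_pool(F, p = 3),
                 tolerance = 1e-9)
})

test_that("triple pooling is ordered GeM, GAP, GMP and obeys the power-mean
           inequality on random maps", {
  F <- array(c(1, 2, 3, 4), c(2, 2, 1))
  expect_equal(pool_triplet(F, p = 3),
               c(((1 + 8 + 27 + 64) / 4)^(1 / 3), 2.5, 4))
  Fc <- array(1.3, c(4, 4, 2))
  expect_equal(pool_triplet(Fc, p = 2), rep(1.3, 6))
  set.seed(42)
  for (i in 1:1000) {
    Fr <- array(abs(stats::rnorm(4 * 4 * 2)), c(4, 4, 2))
    pools <- matrix(pool_triplet(Fr, p = stats::runif(1, 1, 6)), ncol = 3)
    expect_true(all(pools[, 2] <= pools[, 1] + 1e-9))  # GAP <= GeM
    expect_true(all(pools[, 1] <= pools[, 3] + 1e-9))  # GeM <= GMP
  }
})

test_that("descriptor projection yields a 128-d layer-normalized embedding
           for either branch width", {
  for (in_dim in c(3 * 1280, 3 * 576)) {
    w <- descriptor_weights(in_dim, 128, seed = 3)
    set.seed(1)
    pools <- abs(stats::rnorm(in_dim))
    d <- project_descriptor(pools, w)
    expect_length(d, 128)
    # undo the affine to check the normalization core
    core <- (d - w$ln_beta) / w$ln_gamma
    expect_equal(mean(core), 0, tolerance = 1e-6)
    expect_equal(mean(core^2), 1, tolerance = 1e-3)
    expect_identical(d, project_descriptor(pools, w))
  }
  w <- descriptor_weights(12, 8)
  expect_error(project_descriptor(numeric(10), w), "does not match")
})

test_that("the batched branch path agrees with the composed single-map ops", {
  par <- bilight:::init_head_params(4L, 3L, dim = 8L, n_classes = 3L, seed = 9)
  F <- rand_fmap(3, 3, 4, seed = 11)
  F4 <- array(F, c(1, dim(F)))
  batch <- bilight:::branch_forward(F4, par, "a")
  Ft <- eca_rescale(F, kernel = par$a_eca)
  pools <- pool_triplet(Ft, p = as.numeric(par$a_gem_p))
  d <- project_descriptor(pools, list(W = par$a_W1, b = par$a_b1,
                                      ln_gamma = par$a_ln_g,
                                      ln_beta = par$a_ln_b))
  expect_equal(as.vector(batch$D), as.vector(d), tolerance = 1e-12,
               ignore_attr = TRUE)
})
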