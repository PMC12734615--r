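# Backbone registry, feature extraction, and the parameter audit.

test_that("canonical layouts reproduce the published topless parameter
           counts", {
  a <- sum(vapply(bilight:::effnetv2_b0_layers(),
                  bilight:::layer_param_count, numeric(1)))
  b <- sum(vapply(bilight:::mobilenetv3_small_layers(),
                  bilight:::layer_param_count, numeric(1)))
  expect_identical(a, 5919312)
  expect_identical(b, 939120)
})

test_that("stub feature extraction has the contracted shape and is
           deterministic", {
  bk <- build_backbone("stub", seed = 4)
  img <- array(0, c(224, 224, 3))
  f <- extract_features(img, bk)
  expect_equal(dim(f), c(1, 14, 14, bk$output_channels))
  expect_true(all(is.finite(f)))
  set.seed(1)
  img2 <- array(stats::runif(224 * 224 * 3), c(224, 224, 3))
  f1 <- extract_features(img2, bk)
  f2 <- extract_features(img2, bk)
  expect_identical(f1, f2)
  # two identical images in one batch give bit-identical maps
  fb <- extract_features(list(img2, img2), bk)
  expect_identical(fb[1, , , ], fb[2, , , ])
})

test_that("canonical backbones map a 224 input to their contracted grids", {
  img <- array(0, c(224, 224, 3))
  fb <- extract_features(img, build_backbone("mobilenetv3_small", seed = 1))
  expect_equal(dim(fb), c(1, 7, 7, 576))
  expect_true(all(is.finite(fb)))
  fa <- extract_features(img, build_backbone("effnetv2_b0", seed = 1))
  expect_equal(dim(fa), c(1, 7, 7, 1280))
  expect_true(all(is.finite(fa)))
})

test_that("wrong spatial size is rejected with a message naming the
           expected size", {
  bk <- build_backbone("stub", seed = 1)
  expect_error(extract_features(array(0, c(112, 112, 3)), bk), "224x224")
  expect_error(extract_features(array(0, c(224, 224, 4)), bk), "224x224x3")
})

test_that("user-registered backbones are usable as branches", {
  register_backbone("tiny_test", function()
    list(bilight:::layer_conv(3, 32, 3, 4, act = "relu", bn = FALSE,
                              bias = TRUE)))
  bk <- build_backbone("tiny_test", seed = 2)
  f <- extract_features(array(0.5, c(224, 224, 3)), bk)
  expect_equal(dim(f), c(1, 7, 7, 4))
  expect_error(build_backbone("nonexistent"), "unknown backbone")
})

test_that("audit conserves totals and flags the head running statistics as
           the only non-frozen non-trainables", {
  m <- bilight_model("stub", "stub", seed = 3)
  aud <- audit_parameters(m)
  expect_equal(aud$total, aud$trainable + aud$non_trainable)
  expect_equal(sum(aud$by_component), aud$total)
  backbone_total <- aud$by_component[["backbone_a"]] +
    aud$by_component[["backbone_b"]]
  expect_equal(aud$non_trainable, backbone_total + 256)
  expect_equal(aud$size_mib, aud$total * 4 / 2^20)
})

test_that("frozen backbones are bit-identical after a full training run", {
  td <- shared_dataset()
  cfg <- stub_config(epochs = 1)
  fit <- bilight(td, cfg)
  ref_a <- build_backbone("stub", seed = bilight:::mix_seed(cfg$seed, 1))
  expect_identical(fit$model$backbone_a$params, ref_a$params)
  ref_b <- build_backbone("stub", seed = bilight:::mix_seed(cfg$seed, 2))
  expect_identical(fit$model$backbone_b$params, ref_b$params)
})
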