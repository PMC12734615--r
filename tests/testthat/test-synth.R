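# Synthetic tile generator, dataset writer, and the stratified split.

test_that("tiles are deterministic per (class, size, seed) and classes are
           validated", {
  t1 <- generate_tile("colon_n", seed = 5)
  t2 <- generate_tile("colon_n", seed = 5)
  expect_identical(t1, t2)
  t3 <- generate_tile("colon_n", seed = 6)
  expect_false(identical(t1$image, t3$image))
  expect_error(generate_tile("kidney"), "unknown class")
  expect_true(all(t1$image >= 0 & t1$image <= 1))
})

test_that("every class plants a nonempty structure mask with a bounded
           area fraction", {
  # structures are drawn to a common painted-area target so that tissue
  # coverage itself carries no class information: every class must land in
  # a narrow band just above the target
  for (cl in bilight_classes()) {
    fracs <- vapply(1:20, function(s)
      mean(generate_tile(cl, seed = s)$structure_mask), numeric(1))
    expect_true(all(fracs > 0.30), label = paste(cl, "min fraction"))
    expect_true(all(fracs < 0.45), label = paste(cl, "max fraction"))
  }
})

test_that("background and nuclei separate in hue on a noise-free render", {
  t0 <- generate_tile("lung_n", seed = 3, noise_sd = 0)
  bg <- !t0$structure_mask & !t0$nuclei_mask
  hue_of <- function(maskpx) {
    px <- vapply(1:3, function(ch) mean(t0$image[, , ch][maskpx]), numeric(1))
    grDevices::rgb2hsv(px[1], px[2], px[3], maxColorValue = 1)["h", 1]
  }
  expect_gt(abs(hue_of(bg) - hue_of(t0$nuclei_mask)), 0.05)
})

test_that("the dataset writer emits the class-per-folder layout with a
           reproducible manifest", {
  td <- file.path(tempdir(), "synth-writer")
  unlink(td, recursive = TRUE)
  mf <- generate_dataset(2, seed = 9, out_dir = td)
  expect_equal(nrow(mf), 10)
  for (cl in bilight_classes())
    expect_length(list.files(file.path(td, cl)), 2)
  expect_true(file.exists(file.path(td, "manifest.csv")))
  expect_error(generate_dataset(2, seed = 9, out_dir = td), "overwrite")
  td2 <- file.path(tempdir(), "synth-writer2")
  unlink(td2, recursive = TRUE)
  mf2 <- generate_dataset(2, seed = 9, out_dir = td2)
  expect_identical(mf$class, mf2$class)
  expect_identical(mf$seed, mf2$seed)
  # same seed, same bytes
  expect_identical(readBin(mf$path[1], "raw", 1e6),
                   readBin(mf2$path[1], "raw", 1e6))
  # scanning the bare folder tree (no manifest) recovers the same files
  file.remove(file.path(td2, "manifest.csv"))
  scanned <- read_manifest(td2)
  expect_setequal(basename(scanned$path), basename(mf2$path))
})

test_that("the stratified split is exact, disjoint and deterministic", {
  mf <- data.frame(path = sprintf("t%04d.png", 1:1000),
                   class = rep(bilight_classes(), each = 200))
  sp <- split_dataset(mf, c(0.8, 0.1, 0.1), seed = 11)
  expect_equal(as.vector(table(sp$train$class)), rep(160L, 5))
  expect_equal(as.vector(table(sp$val$class)), rep(20L, 5))
  expect_equal(as.vector(table(sp$test$class)), rep(20L, 5))
  all_paths <- c(sp$train$path, sp$val$path, sp$test$path)
  expect_setequal(all_paths, mf$path)
  expect_equal(anyDuplicated(all_paths), 0)
  sp2 <- split_dataset(mf, c(0.8, 0.1, 0.1), seed = 11)
  expect_identical(sp, sp2)
  expect_false(identical(sp$train$path,
                         split_dataset(mf, seed = 12)$train$path))
  tiny <- data.frame(path = "a", class = "colon_n")
  expect_error(split_dataset(tiny, seed = 1), "fewer than 3")
  expect_error(split_dataset(mf, c(0.5, 0.2, 0.2), seed = 1), "sum to 1")
})

test_that("a 768-pixel tile survives the bilinear resize path into the
           network input size", {
  t768 <- generate_tile("colon_aca", size = 768, seed = 2)
  expect_equal(dim(t768$image), c(768, 768, 3))
  small <- bilinear_resize(t768$image, 224, 224)
  expect_equal(dim(small), c(224, 224, 3))
  expect_true(all(small >= 0 & small <= 1))
})
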