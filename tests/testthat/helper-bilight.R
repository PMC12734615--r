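# Shared fixtures: tiny deterministic feature maps and a small on-disk
# synthetic dataset reused across test files (generated once per session).

rand_fmap <- function(h = 4, w = 4, c = 3, seed = 1, nonneg = TRUE) {
  set.seed(seed)
  v <- stats::rnorm(h * w * c)
  if (nonneg) v <- abs(v)
  array(v, c(h, w, c))
}

# identity-style 1-d fusion weights for scalar probes
scalar_fusion_weights <- function(wh = 1) {
  list(Wg = matrix(0, 2, 1), bg = 0,
       WA = matrix(1, 1, 1), WB = matrix(1, 1, 1),
       Wh = matrix(wh, 1, 1), bh = 0)
}

# small shared dataset on disk (10 tiles/class), built once per test run
shared_dataset <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !dir.exists(dir)) {
      dir <<- file.path(tempdir(), "bilight-shared-data")
      if (!dir.exists(dir))
        generate_dataset(10, seed = 7, out_dir = dir)
    }
    dir
  }
})

stub_config <- function(...) {
  bilight_config(backbone_a = "stub", backbone_b = "stub", seed = 123, ...)
}
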