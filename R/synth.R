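# Procedural generator of five-class histology-like tiles.
#
# Every tile shares an eosin-pink background and scattered purple nuclei;
# each class plants a distinctive architectural signature (regular crypts,
# fused irregular glands, thin-walled alveoli, acinar ring clusters,
# keratin-pearl whorls). The pixels belonging to the planted structures are
# returned as a boolean mask so explainability tests can score saliency
# overlap quantitatively instead of visually.

# Drawing state: an environment holding the image array and masks, painted
# in place through bounding-box local grids so each structure only touches
# the pixels it can reach.
draw_state <- function(size) {
  st <- new.env(parent = emptyenv())
  st$size <- size
  st$img <- array(0, c(size, size, 3))
  for (ch in 1:3) st$img[, , ch] <- c(0.93, 0.76, 0.84)[ch]
  st$smask <- matrix(FALSE, size, size)
  st$nmask <- matrix(FALSE, size, size)
  st
}

# Paint `col` where the shape predicate holds inside the bounding box of a
# center/extent pair; optionally record the painted pixels in a mask.
paint_shape <- function(st, cx, cy, extent, shape_fn, col, jitter = 0,
                        mask = NULL) {
  size <- st$size
  r0 <- max(1L, floor(cx - extent)); r1 <- min(size, ceiling(cx + extent))
  c0 <- max(1L, floor(cy - extent)); c1 <- min(size, ceiling(cy + extent))
  if (r0 > r1 || c0 > c1) return(invisible())
  rows <- r0:r1; cols <- c0:c1
  xg <- matrix(rows, length(rows), length(cols))
  yg <- matrix(rep(cols, each = length(rows)), length(rows), length(cols))
  sel <- shape_fn(xg, yg)
  if (!any(sel)) return(invisible())
  if (jitter > 0) col <- pmin(pmax(col + stats::runif(3, -jitter, jitter), 0), 1)
  for (ch in 1:3) {
    pl <- st$img[rows, cols, ch]; pl[sel] <- col[ch]
    st$img[rows, cols, ch] <- pl
  }
  if (!is.null(mask)) {
    m <- st[[mask]]; sub <- m[rows, cols]; sub[sel] <- TRUE
    m[rows, cols] <- sub; st[[mask]] <- m
  }
  invisible()
}

ann_fn <- function(cx, cy, r, w, ax = 1, ay = 1) function(xg, yg)
  abs(sqrt(((xg - cx) / ax)^2 + ((yg - cy) / ay)^2) - r) < w / 2
disc_fn <- function(cx, cy, r, ax = 1, ay = 1) function(xg, yg)
  ((xg - cx) / ax)^2 + ((yg - cy) / ay)^2 < r^2

#' Generate one synthetic histology tile
#'
#' Renders a deterministic (class, size, seed)-keyed RGB tile in [0, 1]
#' with its planted-structure mask. Class signatures: `colon_n` regular
#' ring-shaped crypts on a jittered lattice; `colon_aca` crowded irregular
#' fused glands; `lung_n` sparse thin-walled polygonal alveoli; `lung_aca`
#' dense acinar clusters of small rings; `lung_scc` concentric
#' keratin-pearl whorls. Gaussian pixel noise (sd `noise_sd`) is added
#' last.
#'
#' @param class_id One of [bilight_classes()].
#' @param size Tile side length in pixels (default 224; use 768 to exercise
#'   the resize path).
#' @param seed Integer seed; identical (class_id, size, seed) triples give
#'   bit-identical tiles and masks.
#' @param noise_sd Gaussian pixel-noise standard deviation (default 0.02).
#' @return List with `image` (size x size x 3), `structure_mask` and
#'   `nuclei_mask` (logical size x size matrices).
#' @export
generate_tile <- function(class_id, size = 224L, seed = 1L, noise_sd = 0.02) {
  classes <- bilight_classes()
  if (!class_id %in% classes)
    stop("unknown class: ", class_id, "; expected one of ",
         paste(classes, collapse = ", "), call. = FALSE)
  ci <- match(class_id, classes)
  sc <- size / 224                      # geometry scales with tile size
  with_seed(mix_seed(seed, ci, size), function() {
    st <- draw_state(size)
    # nuclei: small purple blobs, common to all classes
    for (i in seq_len(round(90 * sc^2))) {
      cx <- stats::runif(1, 3, size - 3); cy <- stats::runif(1, 3, size - 3)
      r <- stats::runif(1, 2, 4) * sc
      paint_shape(st, cx, cy, r + 1, disc_fn(cx, cy, r),
                  c(0.45, 0.30, 0.62), jitter = 0.05, mask = "nmask")
    }
    gland <- c(0.50, 0.25, 0.55)
    # every class plants structure units until a common painted-area
    # target is reached, so tissue coverage itself carries no class
    # information and classes are separable only by structure appearance
    target <- 0.36
    if (class_id == "colon_n") {
      # regular crypts drawn in random order from a jittered lattice
      sp <- 42 * sc
      sites <- expand.grid(x = seq(sp / 2, size - sp / 4, by = sp),
                           y = seq(sp / 2, size - sp / 4, by = sp))
      sites <- sites[sample.int(nrow(sites)), ]
      i <- 0L
      draw_unit <- function() {
        i <<- i + 1L
        if (i <= nrow(sites)) {
          cx <- sites$x[i] + stats::runif(1, -4, 4) * sc
          cy <- sites$y[i] + stats::runif(1, -4, 4) * sc
        } else {
          cx <- stats::runif(1, 15, size - 15)
          cy <- stats::runif(1, 15, size - 15)
        }
        r <- stats::runif(1, 13, 17) * sc
        paint_shape(st, cx, cy, r, disc_fn(cx, cy, r - 2 * sc),
                    c(0.97, 0.93, 0.95), mask = "smask")
        paint_shape(st, cx, cy, r + 2 * sc, ann_fn(cx, cy, r, 4 * sc),
                    gland, jitter = 0.04, mask = "smask")
      }
    } else if (class_id == "colon_aca") {
      # crowded, fused, irregular hyperchromatic glands whose lumina hold
      # dark "dirty necrosis" debris
      draw_unit <- function() {
        cx <- stats::runif(1, 15, size - 15); cy <- stats::runif(1, 15, size - 15)
        r <- stats::runif(1, 8, 20) * sc
        ax <- stats::runif(1, 0.6, 1.5); ay <- stats::runif(1, 0.6, 1.5)
        w <- stats::runif(1, 4, 8) * sc
        paint_shape(st, cx, cy, r * max(ax, ay),
                    disc_fn(cx, cy, r - w / 2, ax, ay),
                    c(0.55, 0.35, 0.45), jitter = 0.05, mask = "smask")
        paint_shape(st, cx, cy, (r + w) * max(ax, ay),
                    ann_fn(cx, cy, r, w, ax, ay), c(0.42, 0.18, 0.48),
                    jitter = 0.08, mask = "smask")
      }
    } else if (class_id == "lung_n") {
      # thin-walled alveoli with clear air spaces
      draw_unit <- function() {
        cx <- stats::runif(1, 25, size - 25); cy <- stats::runif(1, 25, size - 25)
        r <- stats::runif(1, 20, 30) * sc
        paint_shape(st, cx, cy, r, disc_fn(cx, cy, r - 1.5 * sc),
                    c(0.96, 0.90, 0.93), mask = "smask")
        paint_shape(st, cx, cy, r + 2 * sc, ann_fn(cx, cy, r, 2.5 * sc),
                    c(0.75, 0.45, 0.60), jitter = 0.04, mask = "smask")
      }
    } else if (class_id == "lung_aca") {
      # dense acinar clusters: small epithelial discs with ring borders
      draw_unit <- function() {
        ccx <- stats::runif(1, 30, size - 30); ccy <- stats::runif(1, 30, size - 30)
        for (i in 1:9) {
          cx <- ccx + stats::runif(1, -28, 28) * sc
          cy <- ccy + stats::runif(1, -28, 28) * sc
          r <- stats::runif(1, 5, 9) * sc
          paint_shape(st, cx, cy, r, disc_fn(cx, cy, r - 1.5 * sc),
                      c(0.72, 0.48, 0.70), jitter = 0.05, mask = "smask")
          paint_shape(st, cx, cy, r + 2 * sc, ann_fn(cx, cy, r, 3 * sc),
                      gland, jitter = 0.06, mask = "smask")
        }
      }
    } else { # lung_scc: concentric keratin-pearl whorls
      draw_unit <- function() {
        cx <- stats::runif(1, 32, size - 32); cy <- stats::runif(1, 32, size - 32)
        paint_shape(st, cx, cy, 9 * sc, disc_fn(cx, cy, 8 * sc),
                    c(0.95, 0.55, 0.45), jitter = 0.04, mask = "smask")
        for (r in seq(5, 29, by = 6) * sc)
          paint_shape(st, cx, cy, r + 2 * sc, ann_fn(cx, cy, r, 3 * sc),
                      c(0.80, 0.40, 0.50), jitter = 0.04, mask = "smask")
      }
    }
    units <- 0L
    while (mean(st$smask) < target && units < 200L) {
      draw_unit(); units <- units + 1L
    }
    img <- st$img
    if (noise_sd > 0)
      img <- pmin(pmax(img + array(stats::rnorm(length(img), 0, noise_sd),
                                   dim(img)), 0), 1)
    list(image = img, structure_mask = st$smask,
         nuclei_mask = st$nmask & !st$smask)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_per_class` tiles per class in the class-per-folder layout
#' (one subdirectory per class, PNG tiles), the structure masks under
#' `masks/`, and a `manifest.csv` recording per-tile paths, classes, seeds
#' and mask paths. Two runs with the same seed produce identical trees.
#'
#' @param n_per_class Tiles per class (>= 1).
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @param size Tile side length (default 224).
#' @param classes Class labels (default [bilight_classes()]).
#' @param overwrite Allow writing into an existing nonempty directory.
#' @param noise_sd Passed to [generate_tile()].
#' @return The manifest as a data frame (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n_per_class, seed = 1L, out_dir,
                             size = 224L, classes = bilight_classes(),
                             overwrite = FALSE, noise_sd = 0.02) {
  stopifnot(n_per_class >= 1)
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is nonempty; use overwrite = TRUE",
         call. = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    dir.create(file.path(out_dir, cls), showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      ts <- mix_seed(seed, ci * 100003L, i)
      tile <- generate_tile(cls, size = size, seed = ts, noise_sd = noise_sd)
      path <- file.path(out_dir, cls, sprintf("%s_%04d.png", cls, i))
      mpath <- file.path(out_dir, "masks", sprintf("%s_%04d.png", cls, i))
      png::writePNG(tile$image, path)
      png::writePNG(tile$structure_mask * 1, mpath)
      rows[[length(rows) + 1L]] <-
        data.frame(path = path, class = cls, seed = ts, mask_path = mpath,
                   stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a dataset manifest
#'
#' Reads `manifest.csv` when present; otherwise scans a class-per-folder
#' tree (the LC25000 convention: one subdirectory per class containing
#' JPEG/PNG tiles) and builds the manifest from it.
#'
#' @param dir Dataset directory (or a manifest CSV path).
#' @return Data frame with columns `path`, `class`, and when available
#'   `seed` and `mask_path`.
#' @export
read_manifest <- function(dir) {
  if (file.exists(dir) && !dir.exists(dir))
    return(utils::read.csv(dir, stringsAsFactors = FALSE))
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) return(utils::read.csv(mf, stringsAsFactors = FALSE))
  sub <- list.dirs(dir, recursive = FALSE)
  sub <- sub[basename(sub) != "masks"]
  rows <- lapply(sub, function(d) {
    f <- list.files(d, pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE,
                    full.names = TRUE)
    if (!length(f)) return(NULL)
    data.frame(path = f, class = basename(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("no images found under ", dir, call. = FALSE)
  out
}

#' Stratified train/validation/test split
#'
#' Splits a manifest by class into disjoint train/validation/test subsets
#' with the given fractions (default 80/10/10), deterministically for a
#' given seed.
#'
#' @param manifest Data frame with a `class` column.
#' @param fractions Length-3 nonnegative vector summing to 1.
#' @param seed Integer seed.
#' @return List of manifests `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("split fractions must sum to 1", call. = FALSE)
  idx <- list(train = integer(), val = integer(), test = integer())
  for (cls in sort(unique(manifest$class))) {
    rows <- which(manifest$class == cls)
    if (length(rows) < 3L)
      stop("class ", cls, " has fewer than 3 samples", call. = FALSE)
    rows <- with_seed(mix_seed(seed, match(cls, sort(unique(manifest$class)))),
                      function() sample(rows))
    n <- length(rows)
    # every split keeps at least one sample per class
    n_va <- max(1L, round(fractions[2] * n))
    n_tr <- max(1L, min(round(fractions[1] * n), n - n_va - 1L))
    if (n_tr + n_va >= n) n_va <- max(1L, n - n_tr - 1L)
    idx$train <- c(idx$train, rows[seq_len(n_tr)])
    idx$val <- c(idx$val, rows[n_tr + seq_len(n_va)])
    idx$test <- c(idx$test, rows[(n_tr + n_va + 1L):n])
  }
  lapply(idx, function(i) manifest[sort(i), , drop = FALSE])
}

# Load one tile from disk as an (H, W, 3) array in [0, 1], bilinearly
# resized to the network input size when needed.
load_tile <- function(path, input_size = 224L) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3]
  if (dim(img)[1] != input_size || dim(img)[2] != input_size)
    img <- bilinear_resize(img, input_size, input_size)
  img
}
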