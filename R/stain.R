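# Soft H&E stain-space augmentation via optical-density decomposition.
#
# Pixels are mapped to optical density (od = -log10(rgb)), projected onto a
# two-stain hematoxylin/eosin basis, the per-stain concentrations are
# scaled by small random factors, and the image is recomposed. Because only
# the concentration *difference* is re-injected, the map is exactly the
# identity when every factor is 1 (the off-basis residual is preserved).

#' Default H&E optical-density stain basis
#'
#' The standard published hematoxylin/eosin optical-density vectors
#' (Ruifrok-Johnston values), unit-normalized per row. Rows: hematoxylin,
#' eosin; columns: R, G, B.
#'
#' @return A 2x3 matrix with unit-norm rows.
#' @export
stain_basis_he <- function() {
  m <- rbind(hematoxylin = c(0.65, 0.70, 0.29),
             eosin = c(0.07, 0.99, 0.11))
  m / sqrt(rowSums(m^2))
}

#' RGB to optical density
#'
#' `od = -log10(rgb)` per channel, with intensities clamped at 1/255 so the
#' log is finite. White (1,1,1) maps to zero density.
#'
#' @param rgb Numeric vector/array of intensities in (0, 1].
#' @return Nonnegative optical densities, same shape.
#' @export
rgb_to_od <- function(rgb) -log10(pmax(rgb, 1 / 255))

#' Optical density to RGB
#'
#' Inverse of [rgb_to_od()]: `rgb = 10^(-od)`, clamped to [0, 1].
#'
#' @param od Nonnegative optical densities.
#' @return Intensities in [0, 1], same shape.
#' @export
od_to_rgb <- function(od) pmin(pmax(10^(-od), 0), 1)

#' Stain jitter ranges
#'
#' Multiplicative half-widths of the uniform jitter factors: hematoxylin
#' concentration +/-6%, eosin +/-5%, shared stain density +/-4%, brightness
#' +/-2%, contrast +/-3%.
#'
#' @param hematoxylin,eosin,density,brightness,contrast Half-widths in
#'   `[0, 0.5)`.
#' @return Named list of half-widths.
#' @export
jitter_ranges <- function(hematoxylin = 0.06, eosin = 0.05, density = 0.04,
                          brightness = 0.02, contrast = 0.03) {
  r <- list(hematoxylin = hematoxylin, eosin = eosin, density = density,
            brightness = brightness, contrast = contrast)
  stopifnot(all(unlist(r) >= 0), all(unlist(r) < 0.5))
  r
}

#' Apply soft H&E stain jitter to a tile
#'
#' Decomposes the tile into hematoxylin/eosin concentrations against
#' `basis`, multiplies them by independent uniform factors drawn from the
#' configured ranges (plus a shared density factor), recomposes, then
#' applies a brightness factor and a contrast factor about the tile mean.
#' The output is clamped to [0, 1] and is bit-reproducible for a given
#' seed. Applied to training tiles only, never to validation or test data.
#'
#' @param tile An (H, W, 3) RGB array in [0, 1].
#' @param ranges Jitter half-widths from [jitter_ranges()].
#' @param seed Integer seed making the draw deterministic.
#' @param basis 2x3 stain basis (default [stain_basis_he()]).
#' @return Jittered (H, W, 3) array in [0, 1].
#' @export
jitter_tile <- function(tile, ranges = jitter_ranges(), seed = 1L,
                        basis = stain_basis_he()) {
  d <- dim(tile)
  if (length(d) != 3L || d[3] != 3L)
    stop("tile must be an (H, W, 3) RGB array", call. = FALSE)
  f <- with_seed(seed, function() stats::runif(5, -1, 1))
  fh <- 1 + f[1] * ranges$hematoxylin
  fe <- 1 + f[2] * ranges$eosin
  fd <- 1 + f[3] * ranges$density
  fb <- 1 + f[4] * ranges$brightness
  fc <- 1 + f[5] * ranges$contrast
  od <- matrix(rgb_to_od(tile), d[1] * d[2], 3L)
  # least-squares concentrations: conc = od %*% pinv(basis)
  pinv <- t(basis) %*% solve(basis %*% t(basis))
  conc <- od %*% pinv
  conc2 <- cbind(conc[, 1] * fh * fd, conc[, 2] * fe * fd)
  # re-inject only the concentration change; off-basis residual untouched
  od2 <- od + (conc2 - conc) %*% basis
  out <- od_to_rgb(od2)
  out <- out * fb
  out <- (out - mean(out)) * fc + mean(out)
  array(pmin(pmax(out, 0), 1), d)
}
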