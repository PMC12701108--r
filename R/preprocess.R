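# Noise-reduction stage applied to each cropped subtraction image:
# contrast-limited adaptive histogram equalization with an exponential
# target distribution, followed by an alternating sequential filter of
# grayscale openings and closings with disks of increasing radius.

#' Exponential-distribution CLAHE
#'
#' Contrast-limited adaptive histogram equalization. The image is divided
#' into a grid of tiles; each tile's 256-bin histogram is clipped at
#' `clip_limit` (a fraction of the tile pixel count, the clipped excess
#' being redistributed uniformly) and its cumulative distribution is mapped
#' onto the quantile function of a truncated exponential distribution with
#' decay `alpha` on `[0, 1]`. Pixels are remapped by bilinear interpolation
#' between the four surrounding tile mappings, which suppresses tile-border
#' artifacts.
#'
#' @param img 2-D matrix with values in `[0, 1]`.
#' @param tiles integer c(rows, cols) of the tile grid (default c(8, 8)).
#' @param clip_limit histogram clip limit as a fraction of the tile pixel
#'   count (default 0.01).
#' @param alpha exponential decay of the target distribution (default 0.4).
#' @param n_bins histogram bins (default 256).
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
clahe_exponential <- function(img, tiles = c(8L, 8L), clip_limit = 0.01,
                              alpha = 0.4, n_bins = 256L) {
  .assert_matrix(img, "img")
  if (min(img) < 0 || max(img) > 1) stop("clahe_exponential expects unit-range input")
  tr <- as.integer(tiles[1L]); tc <- as.integer(tiles[2L])
  nr <- nrow(img); nc <- ncol(img)
  if (tr > nr || tc > nc) stop("tile grid larger than the image")
  if (alpha <= 0) stop("alpha must be > 0")
  th <- nr / tr; tw <- nc / tc

  bin <- pmin(floor(img * n_bins) + 1L, n_bins)       # 1..n_bins
  row_tile <- pmin(floor((seq_len(nr) - 1L) / th) + 1L, tr)
  col_tile <- pmin(floor((seq_len(nc) - 1L) / tw) + 1L, tc)

  # per-tile clipped-histogram exponential mapping
  scale <- 1 - exp(-alpha)
  lut <- array(0, dim = c(tr, tc, n_bins))
  for (i in seq_len(tr)) {
    for (j in seq_len(tc)) {
      b <- bin[row_tile == i, col_tile == j]
      h <- tabulate(b, nbins = n_bins)
      npx <- length(b)
      limit <- max(clip_limit * npx, 1)
      excess <- sum(pmax(h - limit, 0))
      h <- pmin(h, limit) + excess / n_bins
      cdf <- cumsum(h) / sum(h)
      lut[i, j, ] <- -log(1 - cdf * scale) / alpha
    }
  }

  # bilinear interpolation between tile mappings (clamped at the borders)
  pos_r <- (seq_len(nr) - 0.5) / th + 0.5
  pos_c <- (seq_len(nc) - 0.5) / tw + 0.5
  i0 <- floor(pos_r); fr <- pos_r - i0
  j0 <- floor(pos_c); fc <- pos_c - j0
  i0c <- pmin(pmax(i0, 1L), tr); i1c <- pmin(i0 + 1L, tr)
  j0c <- pmin(pmax(j0, 1L), tc); j1c <- pmin(j0 + 1L, tc)

  I0 <- matrix(i0c, nr, nc); I1 <- matrix(i1c, nr, nc)
  J0 <- matrix(j0c, nr, nc, byrow = TRUE); J1 <- matrix(j1c, nr, nc, byrow = TRUE)
  FR <- matrix(fr, nr, nc); FC <- matrix(fc, nr, nc, byrow = TRUE)
  at <- function(I, J) matrix(lut[cbind(as.vector(I), as.vector(J), as.vector(bin))], nr, nc)
  out <- (1 - FR) * (1 - FC) * at(I0, J0) + (1 - FR) * FC * at(I0, J1) +
         FR * (1 - FC) * at(I1, J0) + FR * FC * at(I1, J1)
  pmin(pmax(out, 0), 1)
}

#' Alternating sequential morphological filter
#'
#' For each radius in `radii` (strictly increasing), applies a grayscale
#' opening followed by a grayscale closing with a Euclidean disk of that
#' radius. Removes bright and dark speckle below the disk scale while
#' preserving larger structures; the output never exceeds the input's
#' extrema.
#'
#' @param img 2-D numeric matrix.
#' @param radii strictly increasing disk radii (default c(1, 2)).
#' @return filtered matrix, same shape.
#' @export
asf_filter <- function(img, radii = c(1L, 2L)) {
  .assert_matrix(img, "img")
  if (length(radii) < 1L || any(diff(radii) <= 0))
    stop("radii must be strictly increasing")
  out <- img
  for (r in radii) {
    k <- disk_kernel(r)
    out <- EBImage::closing(EBImage::opening(out, k), k)
  }
  out
}
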