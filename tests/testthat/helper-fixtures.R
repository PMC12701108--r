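# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the default 20-slice phantom benchmark at the reference seed
bench20 <- function() cached("bench20", generate_benchmark(20, seed = 1))

# a small 3-slice benchmark for pipeline-shape tests
bench3 <- function() cached("bench3", generate_benchmark(3, seed = 5))

# one phantom slice
phantom1 <- function() cached("phantom1", generate_phantom(phantom_config(seed = 7)))

# a rasterized filled disk mask
disk_mask <- function(shape, r0, c0, radius) {
  (row(matrix(0, shape[1], shape[2])) - r0)^2 +
    (col(matrix(0, shape[1], shape[2])) - c0)^2 <= radius^2
}

# brute-force multilevel Otsu over all threshold 4-tuples of an n-bin
# histogram; independent of the dynamic-programming implementation
brute_otsu4 <- function(img, n_bins = 16L) {
  bin <- pmin(floor(img * n_bins) + 1L, n_bins)
  p <- tabulate(bin, n_bins) / length(bin)
  ctr <- (seq_len(n_bins) - 0.5) / n_bins
  best <- -Inf
  best_t <- NULL
  cmb <- utils::combn(n_bins - 1L, 4L)
  for (i in seq_len(ncol(cmb))) {
    t <- cmb[, i]
    lo <- c(1L, t + 1L)
    hi <- c(t, n_bins)
    v <- 0
    ok <- TRUE
    for (k in 1:5) {
      w <- sum(p[lo[k]:hi[k]])
      if (w == 0) { ok <- FALSE; break }
      v <- v + sum(p[lo[k]:hi[k]] * ctr[lo[k]:hi[k]])^2 / w
    }
    if (ok && v > best) { best <- v; best_t <- t }
  }
  list(bins = best_t, objective = best)
}

# exact-conditional one-sided McNemar p by enumeration of all 2^n
# discordance patterns
enum_mcnemar_p <- function(b, c) {
  n <- b + c
  wins <- vapply(0:(2^n - 1), function(x) sum(bitwAnd(x, 2^(0:(n - 1))) > 0), numeric(1))
  mean(wins >= b)
}

# prediction vectors realizing discordant counts (b, c) plus `both` samples
# both classifiers get right
make_discordant <- function(b, c, both = 3L) {
  y <- rep(1L, b + c + both)
  pa <- c(rep(1L, b), rep(0L, c), rep(1L, both))
  pb <- c(rep(0L, b), rep(1L, c), rep(1L, both))
  list(y = y, a = pa, b = pb)
}
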