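# Shared small helpers: disk structuring elements, validation, mask algebra.

#' Euclidean disk structuring element
#'
#' Binary disk kernel containing all offsets with `dx^2 + dy^2 <= r^2`.
#' `disk_kernel(1)` is the 5-pixel cross (4-neighbourhood); `disk_kernel(0)`
#' is a single pixel.
#'
#' @param r non-negative integer radius in pixels.
#' @return a (2r+1) x (2r+1) 0/1 matrix.
#' @export
disk_kernel <- function(r) {
  if (length(r) != 1L || is.na(r) || r < 0) stop("radius must be a single non-negative number")
  r <- as.integer(round(r))
  d <- 2L * r + 1L
  off <- seq_len(d) - r - 1L
  k <- outer(off^2, off^2, `+`) <= r^2
  storage.mode(k) <- "integer"
  k
}

.assert_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) stop(name, " must be a numeric matrix")
  if (any(!is.finite(x))) stop(name, " contains non-finite values")
  invisible(x)
}

.assert_mask <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x)) stop(name, " must be a matrix")
  if (is.logical(x)) return(invisible(x))
  if (is.numeric(x) && all(x %in% c(0, 1))) return(invisible(x))
  stop(name, " must be a logical (or 0/1) matrix")
}

.as_logical_mask <- function(x) {
  if (is.logical(x)) x else x != 0
}

# Translate a logical mask by (dr, dc); pixels shifted outside are dropped
# unless check_bounds, in which case out-of-frame translation is an error.
.translate_mask <- function(mask, dr, dc, check_bounds = FALSE) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (nrow(idx) == 0L) return(out)
  r <- idx[, 1] + dr
  c <- idx[, 2] + dc
  ok <- r >= 1L & r <= nrow(mask) & c >= 1L & c <= ncol(mask)
  if (check_bounds && !all(ok)) stop("translated mask falls outside the frame")
  out[cbind(r[ok], c[ok])] <- TRUE
  out
}

# Deterministic per-item seeds derived from a 32-bit master seed.
.derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 1000003) * 1009 + 97 * as.numeric(i)
  as.integer(s %% 2147483647)
}

.local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
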