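# Core containers: DCE phase stacks, subtraction images, intensity scaling.
#
# Coordinate convention used throughout the package: X = row index (anterior
# chest wall toward row 1), Y = column index (patient right to left). All
# indices are 1-based in the R interface; crop windows are inclusive.

#' Multi-phase DCE-MRI slice stack
#'
#' Container for one axial slice acquired before (phase 1, "Phase 0") and
#' repeatedly after contrast injection. All phases share one shape and
#' non-negative finite intensities.
#'
#' @param phases list of 2-D numeric matrices; element 1 is the pre-contrast
#'   Phase 0 image, followed by at least three post-contrast phases.
#' @param pixel_size_um physical in-plane pixel size in micrometres per pixel
#'   (default 654.762).
#' @param phase_interval_s nominal spacing between dynamic phases in seconds
#'   (default 70).
#' @return an object of class `dce_stack`.
#' @export
dce_stack <- function(phases, pixel_size_um = 654.762, phase_interval_s = 70) {
  if (!is.list(phases) || length(phases) < 4L)
    stop("a DCE stack needs at least 4 phases (Phase 0 + 3 post-contrast)")
  for (i in seq_along(phases)) .assert_matrix(phases[[i]], paste0("phase ", i - 1L))
  shp <- dim(phases[[1L]])
  for (p in phases) if (!identical(dim(p), shp)) stop("all phases must share one shape")
  if (any(vapply(phases, function(p) any(p < 0), logical(1))))
    stop("phase intensities must be non-negative")
  if (length(pixel_size_um) != 1L || pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  structure(
    list(phases = phases, pixel_size_um = pixel_size_um,
         phase_interval_s = phase_interval_s),
    class = "dce_stack")
}

#' @export
print.dce_stack <- function(x, ...) {
  shp <- dim(x$phases[[1L]])
  cat(sprintf("<dce_stack> %d phases (Phase 0 + %d post-contrast), %d x %d px, %.3f um/px\n",
              length(x$phases), length(x$phases) - 1L, shp[1L], shp[2L], x$pixel_size_um))
  invisible(x)
}

#' @export
dim.dce_stack <- function(x) dim(x$phases[[1L]])

#' Number of phases in a stack
#' @param stack a [dce_stack()].
#' @return integer phase count including Phase 0.
#' @export
n_phases <- function(stack) length(stack$phases)

#' Post-contrast subtraction image
#'
#' Subtracts the pre-contrast Phase 0 image from post-contrast phase `k`,
#' clipping negative differences to zero, so that only contrast enhancement
#' remains.
#'
#' @param stack a [dce_stack()].
#' @param k post-contrast phase index (1 = first post-contrast phase; the
#'   default pipeline uses k = 2 and k = 3).
#' @return an object of class `subtraction_image` with fields `values`
#'   (non-negative matrix) and `phase_index`.
#' @export
subtraction_image <- function(stack, k) {
  if (!inherits(stack, "dce_stack")) stop("stack must be a dce_stack")
  if (length(k) != 1L || is.na(k) || k < 1L || k > length(stack$phases) - 1L)
    stop("post-contrast phase index k out of range [1, ", length(stack$phases) - 1L, "]")
  v <- pmax(stack$phases[[k + 1L]] - stack$phases[[1L]], 0)
  structure(list(values = v, phase_index = as.integer(k)), class = "subtraction_image")
}

#' @export
print.subtraction_image <- function(x, ...) {
  cat(sprintf("<subtraction_image> post-contrast phase %d, %d x %d px, max %.4g\n",
              x$phase_index, nrow(x$values), ncol(x$values), max(x$values)))
  invisible(x)
}

#' Affine rescale to the unit interval
#'
#' Maps the minimum to 0 and maximum to 1; a constant image maps to all
#' zeros. Rank order of pixel intensities is preserved.
#'
#' @param img 2-D numeric matrix with finite values.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
to_unit_range <- function(img) {
  .assert_matrix(img, "img")
  rng <- range(img)
  if (rng[2L] == rng[1L]) return(matrix(0, nrow(img), ncol(img)))
  (img - rng[1L]) / (rng[2L] - rng[1L])
}
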