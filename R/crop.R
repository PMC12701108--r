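# Automatic rectangular breast-region cropping. The window is computed from
# the pre-contrast image by scanning for supra-background pixels: the column
# extent of the body (Y_min..Y_max), the most anterior body row (X_min), and
# the chest depth at the median column (X_mid), extended posteriorly by a
# safety margin.

#' Rectangular crop window
#'
#' Inclusive row/column bounds of the breast sub-region. Row index X runs
#' anterior (row 1) to posterior; column index Y runs patient-right to left.
#'
#' @param x_min,x_max inclusive row bounds.
#' @param y_min,y_max inclusive column bounds.
#' @return an object of class `crop_window`.
#' @export
crop_window <- function(x_min, x_max, y_min, y_max) {
  w <- list(x_min = as.integer(x_min), x_max = as.integer(x_max),
            y_min = as.integer(y_min), y_max = as.integer(y_max))
  if (w$x_min > w$x_max || w$y_min > w$y_max) stop("degenerate crop window")
  if (w$x_min < 1L || w$y_min < 1L) stop("crop window outside the image")
  structure(w, class = "crop_window")
}

#' @export
print.crop_window <- function(x, ...) {
  cat(sprintf("<crop_window> rows [%d, %d], cols [%d, %d] (%d x %d px)\n",
              x$x_min, x$x_max, x$y_min, x$y_max,
              x$x_max - x$x_min + 1L, x$y_max - x$y_min + 1L))
  invisible(x)
}

#' Width and height of a crop window
#' @param w a [crop_window()].
#' @return named integer c(rows, cols).
#' @export
window_shape <- function(w) {
  c(rows = w$x_max - w$x_min + 1L, cols = w$y_max - w$y_min + 1L)
}

#' Robust background level estimate
#'
#' Median of the four 8x8 corner patches, a robust stand-in for the air
#' background level when it is not exactly zero.
#'
#' @param img 2-D numeric matrix.
#' @param patch corner patch side length (default 8).
#' @return scalar background intensity.
#' @export
estimate_background <- function(img, patch = 8L) {
  .assert_matrix(img, "img")
  p <- min(patch, nrow(img), ncol(img))
  corners <- c(img[1:p, 1:p], img[1:p, (ncol(img) - p + 1L):ncol(img)],
               img[(nrow(img) - p + 1L):nrow(img), 1:p],
               img[(nrow(img) - p + 1L):nrow(img), (ncol(img) - p + 1L):ncol(img)])
  median(corners)
}

#' Locate the breast-region bounds on a pre-contrast image
#'
#' Scans for pixels whose intensity exceeds `background_level`: `y_min` /
#' `y_max` are the smallest and largest such column indices, `x_min` the
#' smallest such row index, and `x_mid` the smallest such row index within
#' the median column (the chest depth between the breasts). With an even
#' number of columns the lower median column is used.
#'
#' @param img 2-D numeric matrix (typically the Phase 0 image).
#' @param background_level background intensity threshold (default 0, suited
#'   to unit-normalized MR images whose air background is near zero; see
#'   [estimate_background()] for a robust alternative).
#' @return object of class `breast_bounds`: list(x_min, y_min, y_max, x_mid,
#'   median_col).
#' @export
find_breast_bounds <- function(img, background_level = 0) {
  .assert_matrix(img, "img")
  fg <- img > background_level
  if (!any(fg)) stop("empty foreground: no pixel above the background level")
  rows <- which(apply(fg, 1L, any))
  cols <- which(apply(fg, 2L, any))
  med_col <- (ncol(img) + 1L) %/% 2L                  # lower median for even width
  mid_rows <- which(fg[, med_col])
  if (length(mid_rows) == 0L)
    stop("median column contains no supra-background pixel; cannot anchor the chest depth")
  structure(list(x_min = min(rows), y_min = min(cols), y_max = max(cols),
                 x_mid = min(mid_rows), median_col = med_col),
            class = "breast_bounds")
}

#' Build the breast crop window from located bounds
#'
#' The window spans rows `[x_min, x_mid + margin_px]` (clamped to the image)
#' and columns `[y_min, y_max]`. The default 10-pixel margin corresponds to
#' 6.5 mm at the default 654.762 um/px resolution and guards against one
#' breast extending posterior of the mid-column chest depth.
#'
#' @param bounds a `breast_bounds` object from [find_breast_bounds()].
#' @param margin_px posterior safety margin in pixels (default 10).
#' @param image_shape integer c(rows, cols) of the source image.
#' @return a [crop_window()].
#' @export
build_crop_window <- function(bounds, margin_px = 10L, image_shape) {
  stopifnot(inherits(bounds, "breast_bounds"))
  x_max <- min(bounds$x_mid + as.integer(margin_px), image_shape[1L])
  if (x_max < bounds$x_min) stop("degenerate window: x_max above x_min after clamping")
  crop_window(bounds$x_min, x_max, bounds$y_min, bounds$y_max)
}

#' Crop images to a window
#'
#' @param images a single matrix or a list of same-shape matrices.
#' @param w a [crop_window()].
#' @return cropped matrix, or list of cropped matrices, each of shape
#'   `window_shape(w)`.
#' @export
crop_to_window <- function(images, w) {
  stopifnot(inherits(w, "crop_window"))
  one <- function(img) {
    if (w$x_max > nrow(img) || w$y_max > ncol(img)) stop("crop window outside the image")
    img[w$x_min:w$x_max, w$y_min:w$y_max, drop = FALSE]
  }
  if (is.list(images)) lapply(images, one) else one(images)
}
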