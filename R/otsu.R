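# Enhancing-region segmentation: multilevel Otsu thresholding on the two
# pre-processed post-contrast subtraction images and intersection of the
# top-intensity-class masks, so that only regions enhancing at BOTH
# time-points survive.

#' Binary mask container
#'
#' @param values logical matrix.
#' @param provenance one of "otsu2", "otsu3", "intersection" (or free text).
#' @return object of class `binary_mask`.
#' @export
binary_mask <- function(values, provenance = "mask") {
  .assert_mask(values, "values")
  structure(list(values = .as_logical_mask(values), provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s, %d x %d px, %d foreground\n",
              x$provenance, nrow(x$values), ncol(x$values), sum(x$values)))
  invisible(x)
}

#' Multilevel Otsu thresholds
#'
#' Computes `n_thresholds` strictly increasing intensity thresholds that
#' maximize the between-class variance of the image histogram, partitioning
#' the intensity range into `n_thresholds + 1` classes (the default 4
#' thresholds give five classes). The histogram uses `n_bins` equal bins on
#' `[0, 1]`; the exact maximizer is found by dynamic programming over
#' cumulative histogram moments (between-class variance is additive over
#' classes in the sum of weight x mean^2, so boundary-wise DP is exact).
#'
#' @param img 2-D matrix with values in `[0, 1]`; must not be constant.
#' @param n_thresholds number of thresholds (default 4).
#' @param n_bins histogram bins (default 256).
#' @return increasing numeric thresholds (upper bin edges, in intensity
#'   units), with attributes `bins` (boundary bin indices) and
#'   `between_class_variance`.
#' @export
otsu_multilevel <- function(img, n_thresholds = 4L, n_bins = 256L) {
  .assert_matrix(img, "img")
  if (min(img) < 0 || max(img) > 1) stop("otsu_multilevel expects unit-range input")
  if (n_thresholds < 1L) stop("need at least one threshold")
  n_classes <- n_thresholds + 1L
  bin <- pmin(floor(img * n_bins) + 1L, as.integer(n_bins))
  counts <- tabulate(bin, nbins = n_bins)
  if (sum(counts > 0) < 2L) stop("degenerate histogram: image is constant")
  if (sum(counts > 0) < n_classes)
    stop("fewer distinct gray levels (", sum(counts > 0), ") than classes (", n_classes, ")")

  p <- counts / sum(counts)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  cumP <- c(0, cumsum(p))
  cumM <- c(0, cumsum(p * centers))

  # S[i, j]: contribution of a class spanning bins i..j; -Inf forbids empty classes
  wt <- outer(cumP[-1L], cumP[-(n_bins + 1L)], `-`)    # wt[j, i] = P(i..j)
  mu <- outer(cumM[-1L], cumM[-(n_bins + 1L)], `-`)
  S <- ifelse(wt > 0, mu^2 / pmax(wt, .Machine$double.eps), -Inf)  # S[j, i]

  f <- S[, 1L]                                         # one class spanning 1..j
  back <- matrix(0L, n_classes, n_bins)
  for (k in 2L:n_classes) {
    f_new <- rep(-Inf, n_bins)
    for (j in k:n_bins) {
      cand <- f[(k - 1L):(j - 1L)] + S[j, k:j]         # split after bin i = k-1 .. j-1
      best <- which.max(cand)
      f_new[j] <- cand[best]
      back[k, j] <- (k - 1L) + best - 1L               # boundary bin of previous class
    }
    f <- f_new
  }

  bounds <- integer(n_thresholds)
  j <- n_bins
  for (k in n_classes:2L) {
    bounds[k - 1L] <- back[k, j]
    j <- back[k, j]
  }
  thr <- bounds / n_bins
  attr(thr, "bins") <- bounds
  mu_T <- sum(p * centers)
  attr(thr, "between_class_variance") <- f[n_bins] - mu_T^2
  thr
}

#' Top-intensity-class mask
#'
#' Pixels strictly above the largest threshold (ties at the threshold fall
#' to the lower class).
#'
#' @param img 2-D matrix.
#' @param thresholds increasing thresholds from [otsu_multilevel()].
#' @param provenance provenance tag for the mask.
#' @return a [binary_mask()].
#' @export
top_class_mask <- function(img, thresholds, provenance = "otsu") {
  .assert_matrix(img, "img")
  if (length(thresholds) < 1L) stop("thresholds must be non-empty")
  binary_mask(img > max(thresholds), provenance)
}

#' Intersection of two binary masks
#'
#' @param a,b same-shape [binary_mask()] objects.
#' @return a [binary_mask()] with provenance "intersection".
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$values), dim(b$values))) stop("mask shapes differ")
  binary_mask(a$values & b$values, "intersection")
}

#' Segment enhancing candidate regions in one slice
#'
#' Full segmentation stage: crops the breast region (bounds computed on the
#' pre-contrast Phase 0 image), then independently for each configured
#' post-contrast phase (default 2 and 3) forms the subtraction image, crops
#' it, unit-normalizes, applies exponential CLAHE and the alternating
#' sequential filter, takes four-level Otsu thresholds and keeps the
#' top-intensity class; the final mask is the intersection of the per-phase
#' masks, in cropped coordinates.
#'
#' @param stack a [dce_stack()].
#' @param config a [cad_config()] list (segmentation-related entries:
#'   `phases`, `background_level`, `margin_px`, `clahe`, `asf_radii`,
#'   `n_thresholds`).
#' @return object of class `segmentation_result`: list(mask
#'   ([binary_mask()], provenance "intersection"), window
#'   ([crop_window()]), phase0_cropped (unit-range matrix), intermediates
#'   (per phase: filtered image, thresholds, mask)).
#' @export
segment_slice <- function(stack, config = cad_config()) {
  stopifnot(inherits(stack, "dce_stack"))
  phase0 <- to_unit_range(stack$phases[[1L]])
  bg <- config$background_level
  if (identical(bg, "auto")) bg <- estimate_background(phase0)
  bounds <- find_breast_bounds(phase0, bg)
  window <- build_crop_window(bounds, config$margin_px, dim(phase0))

  intermediates <- list()
  masks <- list()
  for (k in config$phases) {
    sub <- subtraction_image(stack, k)
    subc <- crop_to_window(sub$values, window)
    enh <- clahe_exponential(to_unit_range(subc), tiles = config$clahe$tiles,
                             clip_limit = config$clahe$clip_limit,
                             alpha = config$clahe$alpha)
    flt <- asf_filter(enh, config$asf_radii)
    thr <- otsu_multilevel(to_unit_range(flt), config$n_thresholds)
    mk <- top_class_mask(to_unit_range(flt), thr, paste0("otsu", k))
    masks[[as.character(k)]] <- mk
    intermediates[[as.character(k)]] <- list(subtraction = subc, filtered = flt,
                                             thresholds = thr, mask = mk)
  }
  mask <- Reduce(intersect_masks, masks)
  structure(list(mask = mask, window = window, phase0_cropped = crop_to_window(phase0, window),
                 intermediates = intermediates),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d x %d crop, %d enhancing px in intersection\n",
              nrow(x$mask$values), ncol(x$mask$values), sum(x$mask$values)))
  invisible(x)
}
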