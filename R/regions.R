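# Connected-component analysis of the segmentation mask and the first,
# rule-based false-positive reduction stage: reject candidate regions that
# are too small (< 15 px, about 10 mm at the default resolution) or too
# eccentric (> 0.95, typical of vessels and noise streaks).

.moment_ellipse <- function(rows, cols) {
  # central second moments with the 1/12 pixel-extent correction (a single
  # pixel is a unit square, not a point), as in common regionprops tools
  rb <- mean(rows); cb <- mean(cols)
  mu20 <- mean((rows - rb)^2) + 1 / 12
  mu02 <- mean((cols - cb)^2) + 1 / 12
  mu11 <- mean((rows - rb) * (cols - cb))
  common <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  list(centroid = c(row = rb, col = cb),
       major = 4 * sqrt(l1), minor = 4 * sqrt(max(l2, 0)),
       eccentricity = sqrt(max(1 - l2 / l1, 0)))
}

#' Region-of-interest record
#'
#' One connected region: its mask in the (cropped) frame, pixel area,
#' centroid, eccentricity of the second-moment ellipse, provenance
#' ("detected" or "control") and class label ("lesion", "healthy",
#' "unknown").
#'
#' @param mask logical matrix, the region footprint in the full frame.
#' @param provenance "detected" or "control".
#' @param label "lesion", "healthy" or "unknown".
#' @param id optional integer identifier.
#' @return object of class `roi_record` with fields `mask`, `area_px`,
#'   `centroid`, `eccentricity`, `max_dimension` (longest bounding-box
#'   side), `provenance`, `label`, `id`.
#' @export
roi_record <- function(mask, provenance = "detected", label = "unknown", id = NA_integer_) {
  .assert_mask(mask, "mask")
  mask <- .as_logical_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("roi_record requires a non-empty mask")
  mom <- .moment_ellipse(idx[, 1L], idx[, 2L])
  structure(list(
    mask = mask, area_px = nrow(idx), centroid = mom$centroid,
    eccentricity = mom$eccentricity,
    max_dimension = max(diff(range(idx[, 1L])), diff(range(idx[, 2L]))) + 1L,
    provenance = provenance, label = label, id = id), class = "roi_record")
}

#' @export
print.roi_record <- function(x, ...) {
  cat(sprintf("<roi_record #%s> %s/%s, area %d px, ecc %.3f, centroid (%.1f, %.1f)\n",
              x$id, x$provenance, x$label, x$area_px, x$eccentricity,
              x$centroid[1L], x$centroid[2L]))
  invisible(x)
}

# 8-connected labeling built on EBImage's 4-connected bwlabel plus a
# union-find merge across diagonal adjacencies.
.label_components <- function(mask, connectivity = 8L) {
  L <- EBImage::bwlabel(mask * 1)
  L <- matrix(as.integer(round(L)), nrow(mask), ncol(mask))
  if (connectivity == 8L && max(L) > 1L) {
    n <- max(L)
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
    nr <- nrow(L); nc <- ncol(L)
    for (sh in list(c(1L, 1L), c(1L, -1L))) {
      a <- L[1:(nr - 1L), if (sh[2L] > 0) 1:(nc - 1L) else 2:nc]
      b <- L[2:nr, if (sh[2L] > 0) 2:nc else 1:(nc - 1L)]
      sel <- which(a > 0L & b > 0L & a != b)
      for (s in sel) {
        ra <- find(a[s]); rb <- find(b[s])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    L[L > 0L] <- relab[L[L > 0L]]
  }
  L
}

#' Connected-component region properties
#'
#' Labels the connected components of a binary mask (8-connected by
#' default) and returns one [roi_record()] per component with area,
#' centroid and eccentricity (of the ellipse sharing the component's
#' central second moments: 0 for a circle, approaching 1 for a line).
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return list of [roi_record()] (empty list for an empty mask).
#' @export
region_props <- function(mask, connectivity = 8L) {
  v <- if (inherits(mask, "binary_mask")) mask$values else .as_logical_mask(mask)
  .assert_mask(v, "mask")
  if (!any(v)) return(list())
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  L <- .label_components(v, connectivity)
  lapply(seq_len(max(L)), function(i) roi_record(L == i, id = i))
}

#' Rule-based false-positive filter
#'
#' Rejects a candidate region iff its pixel area is strictly below
#' `min_area` or its eccentricity strictly exceeds `max_ecc`; both
#' boundaries keep. At the default 654.762 um/px resolution, 15 px of
#' linear extent corresponds to roughly 10 mm; because the size rule is
#' applied to the pixel *area* by default, an optional `min_max_dimension`
#' (longest bounding-box side, px) is exposed as the length reading.
#'
#' @param rois list of [roi_record()].
#' @param min_area minimum pixel area (default 15).
#' @param max_ecc maximum eccentricity (default 0.95).
#' @param min_max_dimension optional minimum longest-side length in pixels
#'   (NULL, off by default).
#' @return list(kept, rejected): two disjoint lists partitioning the input;
#'   each rejected record gains a `reject_reason` field.
#' @export
rule_filter <- function(rois, min_area = 15L, max_ecc = 0.95, min_max_dimension = NULL) {
  if (min_area < 0 || max_ecc < 0) stop("thresholds must be non-negative")
  kept <- list(); rejected <- list()
  for (roi in rois) {
    reasons <- character(0)
    if (roi$area_px < min_area) reasons <- c(reasons, "min_area")
    if (roi$eccentricity > max_ecc) reasons <- c(reasons, "max_ecc")
    if (!is.null(min_max_dimension) && roi$max_dimension < min_max_dimension)
      reasons <- c(reasons, "min_max_dimension")
    if (length(reasons)) {
      roi$reject_reason <- paste(reasons, collapse = "+")
      rejected[[length(rejected) + 1L]] <- roi
    } else kept[[length(kept) + 1L]] <- roi
  }
  list(kept = kept, rejected = rejected)
}
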