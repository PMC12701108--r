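# Control-ROI construction: every kept suspicious region is duplicated on
# the contralateral breast by reflecting it about the vertical midline of
# the cropped frame and then re-inverting it about its own centroid column,
# which restores the original left-right orientation relative to the
# underlying breast. The two reflections about parallel vertical axes
# compose to a pure horizontal translation, so shape and pixel count are
# conserved exactly.

#' Vertical midline of the cropped frame
#'
#' Real-valued centre column of a cropped frame of the given width
#' (`(width - 1) / 2` in 0-based terms; here returned 1-based as
#' `(width + 1) / 2`), the axis of symmetry between the two breasts.
#'
#' @param window a [crop_window()] or an integer frame width (columns).
#' @return real-valued midline column (1-based).
#' @export
breast_midline <- function(window) {
  width <- if (inherits(window, "crop_window")) unname(window_shape(window)["cols"])
           else as.numeric(window)
  (width + 1) / 2
}

#' Mirror a ROI onto the contralateral breast
#'
#' Reflects the ROI mask about the frame midline `m`, then reflects the
#' result about the vertical line through its own centroid column. Rows are
#' unchanged; the composition is a horizontal translation by
#' `2 * (m - centroid_col)` (rounded to the pixel grid), so the control has
#' the same shape and the same number of pixels as the source.
#'
#' @param roi a [roi_record()] (mask in the cropped frame).
#' @param m midline column from [breast_midline()].
#' @return a [roi_record()] with provenance "control" and label "healthy";
#'   carries the source ROI id in field `source_id`.
#' @export
make_control_roi <- function(roi, m) {
  stopifnot(inherits(roi, "roi_record"))
  idx <- which(roi$mask, arr.ind = TRUE)
  # first reflection: about the frame midline
  c1 <- 2 * m - idx[, 2L]
  # second reflection: about the mirrored region's own centroid column
  c2 <- round(2 * mean(c1) - c1)
  if (any(c2 < 1L | c2 > ncol(roi$mask)))
    stop("control placement error: reflected footprint falls outside the frame")
  out <- matrix(FALSE, nrow(roi$mask), ncol(roi$mask))
  out[cbind(idx[, 1L], c2)] <- TRUE
  if (sum(out) != roi$area_px)
    stop("control construction collision: pixel count not conserved")
  ctrl <- roi_record(out, provenance = "control", label = "healthy", id = roi$id)
  ctrl$source_id <- roi$id
  ctrl
}

#' Build the control-ROI set for kept detections
#'
#' One control per kept ROI. In synthetic mode (when `truth` is supplied)
#' a control overlapping any ground-truth lesion mask is flagged and
#' regenerated with a random row jitter of up to +/-3 px (10 tries), an
#' automated stand-in for the radiologist's visual check that control areas
#' show no suspicious characteristics; an unplaceable control is skipped
#' with a warning.
#'
#' @param kept list of kept [roi_record()] (cropped frame).
#' @param window the [crop_window()] the ROIs live in.
#' @param truth optional `phantom_truth`; its lesion masks (cropped to
#'   `window`) define the conflict test.
#' @param seed integer seed for the jitter RNG (default 1).
#' @return list of control [roi_record()]; each carries `jittered = TRUE`
#'   if the conflict path was taken.
#' @export
build_control_set <- function(kept, window, truth = NULL, seed = 1L) {
  m <- breast_midline(window)
  lesion_union <- NULL
  if (!is.null(truth)) {
    cropped <- lapply(truth$lesion_masks, function(x) crop_to_window(x * 1, window) > 0)
    lesion_union <- Reduce(`|`, cropped, accumulate = FALSE)
  }
  controls <- list()
  .local_seed(seed, for (roi in kept) {
    ctrl <- tryCatch(make_control_roi(roi, m), error = function(e) {
      warning("control for ROI ", roi$id, " skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(ctrl)) next
    if (!is.null(lesion_union) && any(ctrl$mask & lesion_union)) {
      ctrl$jittered <- TRUE
      placed <- FALSE
      for (try in 1:10) {
        dr <- sample(c(-3:-1, 1:3), 1L)
        shifted <- tryCatch(.translate_mask(ctrl$mask, dr, 0L, check_bounds = TRUE),
                            error = function(e) NULL)
        if (!is.null(shifted) && !any(shifted & lesion_union)) {
          ctrl2 <- roi_record(shifted, provenance = "control", label = "healthy", id = roi$id)
          ctrl2$source_id <- roi$id
          ctrl2$jittered <- TRUE
          ctrl <- ctrl2
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        warning("control for ROI ", roi$id, " still overlaps a lesion after 10 jitter tries; skipped")
        next
      }
    }
    controls[[length(controls) + 1L]] <- ctrl
  })
  controls
}
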