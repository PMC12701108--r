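# Readers and writers: NIfTI phase stacks (the field-standard MR volume
# format; phases stacked on the third axis), a plain-text CSV dialect for
# small fixtures, 8-bit PNG masks, CSV ROI/feature tables and
# schema-versioned JSON reports.

#' Write a phase stack
#'
#' NIfTI (`.nii` / `.nii.gz`): phases stacked on the third axis, in-plane
#' pixel size stored in the header (mm). CSV dialect (any other path,
#' treated as a directory): one `phase_XX.csv` per phase plus a
#' `meta.json` with the pixel size and phase interval.
#'
#' @param stack a [dce_stack()].
#' @param path output file (`.nii`/`.nii.gz`) or directory.
#' @return `path`, invisibly.
#' @export
write_series <- function(stack, path) {
  stopifnot(inherits(stack, "dce_stack"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- array(unlist(stack$phases), dim = c(dim(stack$phases[[1L]]), length(stack$phases)))
    img <- RNifti::asNifti(arr)
    px_mm <- stack$pixel_size_um / 1000
    RNifti::pixdim(img) <- c(px_mm, px_mm, 1)
    RNifti::writeNifti(img, path)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(stack$phases)) {
      write.table(stack$phases[[i]], file.path(path, sprintf("phase_%02d.csv", i - 1L)),
                  sep = ",", row.names = FALSE, col.names = FALSE)
    }
    jsonlite::write_json(list(pixel_size_um = stack$pixel_size_um,
                              phase_interval_s = stack$phase_interval_s,
                              n_phases = length(stack$phases)),
                         file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a phase stack
#'
#' Accepts a NIfTI file written by [write_series()] (or any 3-D NIfTI
#' volume whose third axis enumerates phases, Phase 0 first) or a CSV
#' dialect directory. When the NIfTI header carries no usable pixel size
#' (pixdim 1, the format default), the reference resolution of 654.762
#' um/px is assumed with a warning.
#'
#' @param path NIfTI file or CSV-dialect directory.
#' @param default_pixel_size_um fallback pixel size (default 654.762).
#' @return a [dce_stack()].
#' @export
read_series <- function(path, default_pixel_size_um = 654.762) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L) stop("format error: expected a 3-D phase volume")
    if (dim(arr)[3L] < 4L) stop("format error: fewer than 4 phases")
    pd <- RNifti::pixdim(img)
    if (length(pd) < 1L || pd[1L] <= 0 || pd[1L] == 1) {
      warning("no pixel size in NIfTI header; assuming ", default_pixel_size_um, " um/px")
      px <- default_pixel_size_um
    } else px <- pd[1L] * 1000
    phases <- lapply(seq_len(dim(arr)[3L]), function(i) arr[, , i])
    dce_stack(phases, pixel_size_um = px)
  } else {
    meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
    files <- sort(list.files(path, pattern = "^phase_\\d+\\.csv$", full.names = TRUE))
    if (length(files) < 4L) stop("format error: fewer than 4 phase files")
    phases <- lapply(files, function(f) as.matrix(read.csv(f, header = FALSE)))
    phases <- lapply(phases, function(m) { dimnames(m) <- NULL; m })
    dce_stack(phases, pixel_size_um = meta$pixel_size_um,
              phase_interval_s = meta$phase_interval_s)
  }
}

#' Write a binary mask as 8-bit PNG (0/255)
#'
#' @param mask logical matrix or [binary_mask()].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  v <- if (inherits(mask, "binary_mask")) mask$values else .as_logical_mask(mask)
  png::writePNG(v * 1, path)
  invisible(path)
}

#' Read a 0/255 PNG mask
#' @param path `.png` path.
#' @return logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}

.eval_to_list <- function(e) {
  list(classifier = e$classifier, positive = e$positive,
       metrics = as.list(e$metrics), counts = as.list(e$counts),
       mean = as.list(e$mean), sd = as.list(e$sd), auc = e$auc,
       roc = if (!is.null(e$roc)) e$roc else NULL)
}

#' Write an evaluation report (JSON + text table)
#'
#' Serializes the evaluation part of a [run_pipeline()] result (or a
#' single `cad_eval`) to schema-versioned JSON, plus a human-readable
#' text table of accuracy / sensitivity / specificity / precision per
#' classifier next to it (`.txt`).
#'
#' @param report a `cad_run` or `cad_eval` object.
#' @param path output `.json` path.
#' @param roc include ROC points in the JSON (default TRUE).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, roc = TRUE) {
  evals <- if (inherits(report, "cad_eval")) setNames(list(report), report$classifier)
           else report$evals
  if (is.null(evals)) stop("report contains no evaluation results")
  out <- list(schema = "dcecad-report/1",
              classifiers = lapply(evals, .eval_to_list))
  if (!roc) for (i in seq_along(out$classifiers)) out$classifiers[[i]]$roc <- NULL
  if (inherits(report, "cad_run") && !is.null(report$mcnemar))
    out$mcnemar <- lapply(report$mcnemar, function(m) m[c("h", "p", "b", "c", "variant", "alternative")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")

  txt <- c(sprintf("%-12s %9s %12s %12s %10s", "classifier", "accuracy",
                   "sensitivity", "specificity", "precision"),
           vapply(evals, function(e) {
             m <- unlist(e$metrics)
             sprintf("%-12s %9.4f %12.4f %12.4f %10.4f", e$classifier,
                     m[1L], m[2L], m[3L], m[4L])
           }, character(1)))
  writeLines(txt, sub("\\.json$", ".txt", path))
  invisible(path)
}

#' Read a JSON evaluation report
#' @param path `.json` path written by [write_report()].
#' @return nested list mirroring the JSON.
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(out$schema, "dcecad-report/1")) stop("unknown report schema")
  out
}

#' Write all pipeline artifacts for a run
#'
#' Per slice: crop window JSON, intersection mask PNG; pooled: ROI table
#' CSV, feature table CSV, selection JSON and (when the classification
#' stage ran) the evaluation report. Output is deterministic given the
#' run.
#'
#' @param run a `cad_run` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(run, dir) {
  stopifnot(inherits(run, "cad_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roi_rows <- list()
  for (i in seq_along(run$slice_results)) {
    s <- run$slice_results[[i]]
    w <- s$segmentation$window
    jsonlite::write_json(list(x_min = w$x_min, x_max = w$x_max,
                              y_min = w$y_min, y_max = w$y_max),
                         file.path(dir, sprintf("slice_%02d_window.json", i)),
                         auto_unbox = TRUE, digits = NA)
    write_mask_png(s$segmentation$mask, file.path(dir, sprintf("slice_%02d_mask.png", i)))
    for (group in c("kept", "rejected", "controls")) {
      for (roi in s[[group]]) {
        roi_rows[[length(roi_rows) + 1L]] <- data.frame(
          slice = i, id = roi$id, provenance = roi$provenance, label = roi$label,
          area_px = roi$area_px, eccentricity = roi$eccentricity,
          centroid_row = roi$centroid[[1L]], centroid_col = roi$centroid[[2L]],
          kept = group != "rejected")
      }
    }
  }
  if (length(roi_rows))
    write.csv(do.call(rbind, roi_rows), file.path(dir, "rois.csv"), row.names = FALSE)
  if (!is.null(run$feature_table))
    write.csv(run$feature_table, file.path(dir, "features.csv"), row.names = FALSE)
  if (!is.null(run$selection))
    jsonlite::write_json(list(weights = as.list(run$relieff),
                              selected = run$selection$selected,
                              trace = run$selection$trace),
                         file.path(dir, "selection.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(run$evals)) write_report(run, file.path(dir, "report.json"))
  invisible(dir)
}
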