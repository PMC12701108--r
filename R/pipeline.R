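# End-to-end pipeline: segmentation -> rule filter -> control ROIs ->
# features per slice, then pooled feature selection, classification and
# McNemar comparison over a set of slices.

# fraction of the truth region covered by the detection mask
.overlap_fraction <- function(truth_mask, det_mask) {
  sum(truth_mask & det_mask) / sum(truth_mask)
}

# lesion label if at least half the ROI lies on ground-truth lesion tissue
.label_from_truth <- function(roi, lesion_union) {
  if (sum(roi$mask & lesion_union) / roi$area_px >= 0.5) "lesion" else "healthy"
}

#' Process one slice through feature extraction
#'
#' Runs segmentation ([segment_slice()]), connected-component analysis,
#' the rule-based false-positive filter, control-ROI construction and
#' feature extraction for one slice. When ground truth is supplied
#' (synthetic mode) the kept detections are labelled lesion/healthy by
#' majority overlap with the truth lesion masks and controls are checked
#' against the truth.
#'
#' @param stack a [dce_stack()].
#' @param config a [cad_config()].
#' @param truth optional `phantom_truth`.
#' @param seed seed for the control-ROI jitter path.
#' @return object of class `slice_result`: list(segmentation, rois, kept,
#'   rejected, controls, features (data.frame), counters).
#' @export
process_slice <- function(stack, config = cad_config(), truth = NULL, seed = 1L) {
  seg <- segment_slice(stack, config)
  rois <- region_props(seg$mask, config$connectivity)
  for (i in seq_along(rois)) rois[[i]]$id <- i
  flt <- rule_filter(rois, config$min_area, config$max_ecc, config$min_max_dimension)

  lesion_union <- NULL
  if (!is.null(truth)) {
    cropped <- lapply(truth$lesion_masks, function(m) crop_to_window(m * 1, seg$window) > 0)
    lesion_union <- Reduce(`|`, cropped)
    flt$kept <- lapply(flt$kept, function(roi) {
      roi$label <- .label_from_truth(roi, lesion_union)
      roi
    })
  }
  controls <- build_control_set(flt$kept, seg$window, truth, seed = seed)

  all_rois <- c(flt$kept, controls)
  features <- if (length(all_rois))
    build_feature_table(seg$phase0_cropped, all_rois,
                        dilate_radius = config$dilate_radius,
                        grow_radius = config$grow_radius,
                        levels = config$glcm_levels,
                        distances = config$glcm_distances,
                        extras = config$feature_extras)
  else NULL

  counters <- c(found = length(rois), kept = length(flt$kept),
                rejected = length(flt$rejected), controls = length(controls))
  structure(list(segmentation = seg, rois = rois, kept = flt$kept,
                 rejected = flt$rejected, controls = controls,
                 features = features, counters = counters),
            class = "slice_result")
}

#' @export
print.slice_result <- function(x, ...) {
  cat(sprintf("<slice_result> %d candidate regions, %d kept, %d rejected, %d controls\n",
              x$counters["found"], x$counters["kept"], x$counters["rejected"],
              x$counters["controls"]))
  invisible(x)
}

#' Run the CAD pipeline over a set of slices
#'
#' Per slice: crop, pre-process, segment, rule-filter, build controls,
#' extract features. Over the pooled per-ROI feature table: ReliefF
#' ranking, sequential backward feature selection, FFBPN (both hidden
#' sizes) and SMOTE-balanced SVM training/evaluation, and McNemar
#' comparisons of the SVM against each network (exact-conditional and
#' mid-p, one-sided "SVM better"). All randomness derives from `seed`.
#'
#' @param slices a list whose elements are either [dce_stack()] objects or
#'   list(stack, truth) pairs as returned by [generate_phantom()] /
#'   [generate_benchmark()].
#' @param config a [cad_config()].
#' @param seed master seed.
#' @param stop_after optionally halt after a stage: "features" (default
#'   full run), "segment", "rules", "controls".
#' @return object of class `cad_run`: list(slice_results, feature_table,
#'   relieff, selection, evals, mcnemar, config, seed, stopped_after).
#' @export
run_pipeline <- function(slices, config = cad_config(), seed = 1L,
                         stop_after = c("classify", "segment", "rules", "controls", "features")) {
  stop_after <- match.arg(stop_after)
  stage_rank <- c(segment = 1L, rules = 2L, controls = 3L, features = 4L, classify = 5L)
  depth <- stage_rank[[stop_after]]

  norm <- lapply(slices, function(s) {
    if (inherits(s, "dce_stack")) list(stack = s, truth = NULL) else s
  })

  results <- vector("list", length(norm))
  for (i in seq_along(norm)) {
    s <- norm[[i]]
    if (depth <= 1L) {
      seg <- segment_slice(s$stack, config)
      results[[i]] <- structure(list(segmentation = seg), class = "slice_result")
    } else {
      results[[i]] <- tryCatch(
        process_slice(s$stack, config, s$truth, seed = .derive_seed(seed, i)),
        error = function(e) stop("slice ", i, " [pipeline]: ", conditionMessage(e)))
    }
  }
  run <- structure(list(slice_results = results, config = config, seed = seed,
                        stopped_after = stop_after),
                   class = "cad_run")
  if (depth < 4L) return(run)

  tabs <- Filter(Negate(is.null), lapply(seq_along(results), function(i) {
    ft <- results[[i]]$features
    if (!is.null(ft)) cbind(slice = i, ft) else NULL
  }))
  if (!length(tabs)) stop("no ROIs survived the rule stage: empty feature table")
  feature_table <- do.call(rbind, tabs)
  run$feature_table <- feature_table
  if (depth < 5L) return(run)

  feat_cols <- setdiff(names(feature_table), c("slice", "id", "provenance", "label"))
  X <- as.matrix(feature_table[, feat_cols])
  y <- factor(feature_table$label, levels = c("healthy", "lesion"))
  if (nlevels(droplevels(y)) < 2L)
    stop("classification stage needs both lesion and healthy ROIs (supply ground truth)")

  k_eff <- min(config$relieff_k, min(table(droplevels(y))) - 1L)
  run$relieff <- sort(relieff_weights(X, y, k = k_eff), decreasing = TRUE)
  run$selection <- sequential_backward_select(X, y, folds = config$folds,
                                              seed = .derive_seed(seed, 1001L))
  Xsel <- X[, run$selection$selected, drop = FALSE]

  evals <- list()
  for (h in config$hidden) {
    evals[[paste0("ffbpn_", h)]] <- train_eval_ffbpn(
      Xsel, y, positive = "lesion", hidden_n = h, repeats = config$repeats,
      seed = .derive_seed(seed, 2000L + h))
  }
  evals$svm <- train_eval_svm(Xsel, y, positive = "lesion", folds = config$folds,
                              seed = .derive_seed(seed, 3000L))
  run$evals <- evals

  # McNemar: SVM (A) vs each network (B) on the network's first held-out
  # test split; the SVM predictions there are out-of-fold, so both sides
  # are honest held-out predictions on the same samples.
  run$mcnemar <- list()
  svm_pred <- evals$svm$predictions
  for (h in config$hidden) {
    nn <- evals[[paste0("ffbpn_", h)]]$predictions
    nn1 <- nn[nn$repeat_ == 1L, ]
    idx <- nn1$idx
    svm_at <- svm_pred$pred[match(idx, svm_pred$idx)]
    for (variant in c("exact", "midp")) {
      key <- paste0("svm_vs_ffbpn", h, "_", variant)
      run$mcnemar[[key]] <- mcnemar_test(nn1$truth, svm_at, nn1$pred,
                                         variant = variant, alternative = "a.better")
    }
  }
  run
}

#' @export
print.cad_run <- function(x, ...) {
  cat(sprintf("<cad_run> %d slices, stage reached: %s\n",
              length(x$slice_results), x$stopped_after))
  if (!is.null(x$feature_table))
    cat(sprintf("  feature table: %d ROIs (%d detected / %d control)\n",
                nrow(x$feature_table), sum(x$feature_table$provenance == "detected"),
                sum(x$feature_table$provenance == "control")))
  if (!is.null(x$selection))
    cat("  selected features:", paste(x$selection$selected, collapse = ", "), "\n")
  if (!is.null(x$evals)) for (ev in x$evals) print(ev)
  invisible(x)
}

#' @export
summary.cad_run <- function(object, ...) {
  cnt <- t(vapply(object$slice_results, function(s) {
    if (!is.null(s$counters)) s$counters else c(found = NA, kept = NA, rejected = NA, controls = NA)
  }, numeric(4)))
  out <- list(n_slices = length(object$slice_results), counters = cnt,
              selected = object$selection$selected,
              metrics = if (!is.null(object$evals))
                do.call(rbind, lapply(object$evals, function(e)
                  cbind(classifier = e$classifier, e$metrics, auc = e$auc))),
              mcnemar = if (!is.null(object$mcnemar))
                do.call(rbind, lapply(names(object$mcnemar), function(k) {
                  m <- object$mcnemar[[k]]
                  data.frame(comparison = k, h = m$h, p = m$p, b = m$b, c = m$c)
                })))
  class(out) <- "summary.cad_run"
  out
}

#' @export
print.summary.cad_run <- function(x, ...) {
  cat(sprintf("CAD pipeline run over %d slices\n", x$n_slices))
  cat(sprintf("  candidate ROIs: %d found, %d kept, %d rejected, %d controls\n",
              sum(x$counters[, "found"]), sum(x$counters[, "kept"]),
              sum(x$counters[, "rejected"]), sum(x$counters[, "controls"])))
  if (!is.null(x$selected))
    cat("  selected features:", paste(x$selected, collapse = ", "), "\n")
  if (!is.null(x$metrics)) { cat("  classification (pooled held-out):\n"); print(x$metrics, row.names = FALSE) }
  if (!is.null(x$mcnemar)) { cat("  McNemar (one-sided, SVM better):\n"); print(x$mcnemar, row.names = FALSE) }
  invisible(x)
}

#' Segmentation-stage detection check against ground truth
#'
#' For every truth lesion of a benchmark, computes the fraction of its
#' pixels covered by the intersection mask and flags it detected when the
#' coverage reaches `min_overlap`.
#'
#' @param benchmark list of list(stack, truth) as from [generate_benchmark()].
#' @param config a [cad_config()].
#' @param min_overlap detection convention (default 0.5).
#' @return data.frame: slice, lesion, kinetic, area_px, overlap, detected.
#' @export
evaluate_detection <- function(benchmark, config = cad_config(), min_overlap = 0.5) {
  rows <- list()
  for (i in seq_along(benchmark)) {
    s <- benchmark[[i]]
    seg <- segment_slice(s$stack, config)
    for (j in seq_along(s$truth$lesion_masks)) {
      m <- s$truth$lesion_masks[[j]]
      mc <- crop_to_window(m * 1, seg$window) > 0
      ov <- .overlap_fraction(mc, seg$mask$values)
      rows[[length(rows) + 1L]] <- data.frame(
        slice = i, lesion = j, kinetic = attr(m, "kinetic"),
        area_px = attr(m, "area"), overlap = ov, detected = ov >= min_overlap)
    }
  }
  do.call(rbind, rows)
}
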