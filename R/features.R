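# Per-ROI feature extraction on the pre-contrast Phase 0 image: 12 GLCM
# texture statistics (6 statistics x 2 pixel distances, averaged over the
# 0/45/90/135 degree directions) plus two ring-contrast ratios. ROIs are
# dilated by a 1-px disk first to absorb minor patient movement between the
# pre- and post-contrast phases.

#' Dilate a binary mask with a disk
#'
#' @param mask logical matrix.
#' @param radius disk radius in pixels (default 1; 0 is the identity).
#' @return logical matrix containing the input.
#' @export
dilate_mask <- function(mask, radius = 1L) {
  .assert_mask(mask, "mask")
  if (radius < 0) stop("radius must be non-negative")
  m <- .as_logical_mask(mask)
  if (radius == 0L || !any(m)) return(m)
  .as_logical_mask(EBImage::dilate(m * 1, disk_kernel(radius)) > 0)
}

#' Surrounding ring of a ROI
#'
#' Grows the mask with a disk of `grow_radius` pixels and subtracts the
#' original mask, producing a ring of surrounding tissue (clipped at the
#' frame borders). The default radius of 4 px reflects the typical
#' area-to-perimeter ratio of the detected lesions.
#'
#' @param mask logical matrix.
#' @param grow_radius disk radius for the growth step (default 4).
#' @return logical ring mask, disjoint from `mask` (empty for an empty mask).
#' @export
ring_mask <- function(mask, grow_radius = 4L) {
  .assert_mask(mask, "mask")
  m <- .as_logical_mask(mask)
  if (!any(m)) return(m & FALSE)
  dilate_mask(m, grow_radius) & !m
}

# offsets for the standard GLCM directions (row, col), image convention
.glcm_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d),
         stop("unsupported GLCM angle: ", angle))
}

.glcm_stats <- function(P, warn_constant = TRUE) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_ <- rowSums(P)
  mu_i <- sum(seq_len(L) * pi_)
  sd_i <- sqrt(sum((seq_len(L) - mu_i)^2 * pi_))
  correlation <- if (sd_i == 0) {
    if (warn_constant) warning("constant ROI intensity: GLCM correlation undefined, returned as 0")
    0
  } else sum((i - mu_i) * (j - mu_i) * P) / sd_i^2     # symmetric P: mu_j = mu_i
  pz <- P[P > 0]
  c(contrast = sum(P * (i - j)^2),
    correlation = correlation,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))),
    entropy = -sum(pz * log2(pz)),
    idm = sum(P / (1 + (i - j)^2)))
}

#' GLCM texture features of a masked region
#'
#' Intensities inside the mask are quantized to `levels` gray levels over
#' the region's min-max range. For every distance and direction a
#' symmetric, normalized gray-level co-occurrence matrix is accumulated
#' from pixel pairs that both lie inside the mask; the six statistics
#' (contrast, correlation, energy, homogeneity, entropy in bits, inverse
#' difference moment) are averaged over the four directions per distance.
#'
#' @param img 2-D intensity matrix covering the mask (typically Phase 0).
#' @param mask logical matrix, non-empty.
#' @param levels gray levels for quantization (default 8).
#' @param distances pixel distances (default c(1, 2)).
#' @param angles directions in degrees (default c(0, 45, 90, 135)).
#' @return named numeric vector of length `6 * length(distances)`, names
#'   `<stat>_d<distance>`.
#' @export
glcm_features <- function(img, mask, levels = 8L, distances = c(1L, 2L),
                          angles = c(0, 45, 90, 135)) {
  .assert_matrix(img, "img")
  .assert_mask(mask, "mask")
  m <- .as_logical_mask(mask)
  if (!any(m)) stop("mask is empty")
  if (!identical(dim(img), dim(m))) stop("img and mask shapes differ")
  vals <- img[m]
  rng <- range(vals)
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  q[m] <- if (rng[2L] > rng[1L])
    pmin(floor((vals - rng[1L]) / (rng[2L] - rng[1L]) * levels) + 1L, as.integer(levels))
  else 1L

  idx <- which(m, arr.ind = TRUE)
  out <- numeric(0)
  warned <- FALSE
  for (d in distances) {
    acc <- matrix(0, 6L, length(angles))
    for (a in seq_along(angles)) {
      off <- .glcm_offset(angles[a], as.integer(d))
      r2 <- idx[, 1L] + off[1L]; c2 <- idx[, 2L] + off[2L]
      ok <- r2 >= 1L & r2 <= nrow(img) & c2 >= 1L & c2 <= ncol(img)
      ok[ok] <- m[cbind(r2[ok], c2[ok])]
      if (!any(ok))
        stop("degenerate pairs: no in-mask pixel pairs at distance ", d,
             ", angle ", angles[a])
      gi <- q[idx[ok, , drop = FALSE]]
      gj <- q[cbind(r2[ok], c2[ok])]
      cnt <- tabulate((gi - 1L) * levels + gj, nbins = levels^2)
      G <- matrix(cnt, levels, levels, byrow = TRUE)
      G <- G + t(G)                                    # symmetric
      # muffle per-direction warnings; one summary warning is raised below
      st <- withCallingHandlers(
        .glcm_stats(G / sum(G), warn_constant = !warned),
        warning = function(w) { warned <<- TRUE; invokeRestart("muffleWarning") })
      acc[, a] <- st
    }
    avg <- rowMeans(acc)
    names(avg) <- paste0(c("contrast", "correlation", "energy", "homogeneity",
                           "entropy", "idm"), "_d", d)
    out <- c(out, avg)
  }
  if (warned) warning("constant ROI intensity: GLCM correlation undefined, returned as 0")
  out
}

#' Ring-contrast features
#'
#' `CON = (I_in - I_r) / (I_in + I_r)` and
#' `C = (I_in - I_r)^2 / (sigma_in^2 + sigma_r^2)`, where `I`/`sigma` are
#' the mean and standard deviation of the intensities inside the ROI
#' (`in`) and inside its surrounding ring (`r`).
#'
#' @param img 2-D intensity matrix.
#' @param mask logical ROI mask, non-empty.
#' @param ring logical ring mask, non-empty, disjoint from `mask`.
#' @return list(con, c, mean_in, sd_in, mean_ring, sd_ring).
#' @export
contrast_features <- function(img, mask, ring) {
  .assert_matrix(img, "img")
  m <- .as_logical_mask(mask); rg <- .as_logical_mask(ring)
  if (!any(m) || !any(rg)) stop("mask and ring must be non-empty")
  if (any(m & rg)) stop("mask and ring must be disjoint")
  i_in <- mean(img[m]); i_r <- mean(img[rg])
  s_in <- if (sum(m) > 1L) sd(img[m]) else 0
  s_r <- if (sum(rg) > 1L) sd(img[rg]) else 0
  if (i_in + i_r == 0) stop("CON undefined: I_in + I_r = 0")
  if (s_in^2 + s_r^2 == 0) stop("C undefined: sigma_in^2 + sigma_r^2 = 0")
  list(con = (i_in - i_r) / (i_in + i_r),
       c = (i_in - i_r)^2 / (s_in^2 + s_r^2),
       mean_in = i_in, sd_in = s_in, mean_ring = i_r, sd_ring = s_r)
}

#' Extract the per-ROI feature vector
#'
#' Dilates the ROI by a 1-px disk, computes the 12 GLCM texture features
#' on the dilated footprint and the two ring-contrast ratios against the
#' 4-px growth ring, all on the pre-contrast image: 14 features by
#' default. The ROI mean and standard deviation can be appended as
#' optional extras.
#'
#' @param img pre-contrast (Phase 0) intensity matrix in the same frame as
#'   the ROI.
#' @param roi a [roi_record()].
#' @param dilate_radius movement-tolerance dilation (default 1).
#' @param grow_radius ring growth radius (default 4).
#' @param levels,distances,angles passed to [glcm_features()].
#' @param extras append ROI mean and sd (default FALSE).
#' @return named numeric vector, length 14 (16 with `extras`).
#' @export
extract_feature_vector <- function(img, roi, dilate_radius = 1L, grow_radius = 4L,
                                   levels = 8L, distances = c(1L, 2L),
                                   angles = c(0, 45, 90, 135), extras = FALSE) {
  stopifnot(inherits(roi, "roi_record"))
  dil <- dilate_mask(roi$mask, dilate_radius)
  ring <- ring_mask(dil, grow_radius)
  tex <- glcm_features(img, dil, levels = levels, distances = distances, angles = angles)
  con <- contrast_features(img, dil, ring)
  v <- c(tex, con = con$con, c = con$c)
  if (extras) v <- c(v, mean_in = con$mean_in, sd_in = con$sd_in)
  v
}

#' Feature table for a set of ROIs
#'
#' @param img pre-contrast image in the ROI frame.
#' @param rois list of [roi_record()].
#' @param ... passed to [extract_feature_vector()].
#' @return data.frame: id, provenance, label, then one column per feature.
#' @export
build_feature_table <- function(img, rois, ...) {
  rows <- lapply(rois, function(roi) {
    v <- extract_feature_vector(img, roi, ...)
    cbind(data.frame(id = roi$id, provenance = roi$provenance, label = roi$label,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}
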