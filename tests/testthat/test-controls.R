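test_that("midline sits at the real-valued centre column", {
  expect_equal(breast_midline(91), 46)                 # odd width: centre column
  expect_equal(breast_midline(90), 45.5)               # even width: half-way
  w <- crop_window(1, 10, 1, 91)
  expect_equal(breast_midline(w), 46)
  # reflection about the midline maps the first column to the last
  expect_equal(2 * breast_midline(91) - 1, 91)
})

test_that("two-reflection control equals a pure horizontal translation", {
  set.seed(9)
  for (i in 1:100) {
    fr_rows <- 40L; fr_cols <- 80L
    r0 <- sample(8:32, 1)
    c0 <- sample(8:30, 1)
    a <- sample(2:5, 1); b <- sample(2:5, 1)
    m <- matrix(FALSE, fr_rows, fr_cols)
    m <- ((row(m) - r0) / a)^2 + ((col(m) - c0) / b)^2 <= 1
    if (!any(m)) next
    roi <- roi_record(m)
    mid <- breast_midline(fr_cols)
    ctrl <- make_control_roi(roi, mid)
    expect_equal(ctrl$area_px, roi$area_px)            # pixel count conserved
    shift <- round(2 * (mid - roi$centroid[["col"]]))
    translated <- dcecad:::.translate_mask(roi$mask, 0L, shift)
    expect_identical(ctrl$mask, translated)
    expect_equal(ctrl$centroid[["row"]], roi$centroid[["row"]])
    # applying the construction again returns the original footprint
    expect_identical(make_control_roi(ctrl, mid)$mask, roi$mask)
  }
})

test_that("a ROI symmetric about its own axis mirrors about the midline alone", {
  m <- matrix(FALSE, 20, 40)
  m[8:12, 6:10] <- TRUE                                # symmetric rectangle
  roi <- roi_record(m)
  ctrl <- make_control_roi(roi, breast_midline(40))
  pure_mirror <- m[, 40:1]
  expect_identical(ctrl$mask, pure_mirror)
})

test_that("controls carry provenance/label and out-of-frame placement errors", {
  m <- matrix(FALSE, 20, 40)
  m[5:8, 3:6] <- TRUE
  roi <- roi_record(m, label = "lesion")
  ctrl <- make_control_roi(roi, breast_midline(40))
  expect_equal(ctrl$provenance, "control")
  expect_equal(ctrl$label, "healthy")
  expect_error(make_control_roi(roi, 45), "outside the frame")
})

test_that("control set pairs kept ROIs and jitters off conflicting truth", {
  w <- crop_window(1, 40, 1, 80)
  m <- matrix(FALSE, 40, 80)
  m[disk_mask(c(40, 80), 20, 22, 4)] <- TRUE
  roi <- roi_record(m, label = "lesion", id = 1L)
  plain <- build_control_set(list(roi), w)
  expect_length(plain, 1L)
  expect_equal(plain[[1]]$area_px, roi$area_px)

  # a truth lesion grazing the mirrored position forces the jitter path; a
  # thin sliver so a few pixels of row jitter can clear it
  mirrored <- make_control_roi(roi, breast_midline(w))$mask
  sliver <- mirrored & row(mirrored) == max(which(mirrored, arr.ind = TRUE)[, 1])
  truth <- structure(list(lesion_masks = list(sliver)), class = "phantom_truth")
  jit <- build_control_set(list(roi), w, truth = truth, seed = 2)
  expect_length(jit, 1L)
  expect_true(isTRUE(jit[[1]]$jittered))
  expect_false(any(jit[[1]]$mask & sliver))
  expect_equal(jit[[1]]$area_px, roi$area_px)
})
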