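test_that("four thresholds separate five flat intensity blocks exactly", {
  img <- matrix(rep(c(0.1, 0.3, 0.5, 0.7, 0.9), each = 20), 10, 10)
  thr <- otsu_multilevel(img, 4)
  expect_length(thr, 4L)                               # 4 thresholds = 5 classes
  cls <- findInterval(img, thr)
  expect_equal(length(unique(cls[img == 0.1])), 1L)
  expect_equal(sort(unique(as.vector(tapply(cls, img, unique)))), 0:4)
  expect_true(all((img > max(thr)) == (img == 0.9)))   # top class = brightest block
})

test_that("DP thresholds match exhaustive search on 16-level images", {
  set.seed(7)
  for (r in 1:8) {
    img <- matrix(sample(0:15, 32 * 32, replace = TRUE) / 15, 32, 32)
    thr <- otsu_multilevel(img, 4, n_bins = 16)
    bf <- brute_otsu4(img, 16)
    expect_equal(attr(thr, "bins"), bf$bins)
  }
})

test_that("degenerate histograms are rejected", {
  expect_error(otsu_multilevel(matrix(0.5, 8, 8)), "constant")
  img <- matrix(rep(c(0.2, 0.8), 32), 8, 8)
  expect_error(otsu_multilevel(img, 4), "distinct gray levels")
})

test_that("top-class mask uses a strict threshold and is monotone", {
  img <- matrix(seq(0, 1, length.out = 25), 5, 5)
  m1 <- top_class_mask(img, c(0.2, 0.5))
  expect_true(all(m1$values == (img > 0.5)))
  expect_equal(sum(top_class_mask(img, 0.7)$values) >= sum(top_class_mask(img, 0.8)$values), TRUE)
  expect_equal(sum(top_class_mask(img, 1)$values), 0L)  # all below: legal empty mask
  expect_error(top_class_mask(img, numeric(0)), "non-empty")
})

test_that("mask intersection is idempotent, absorbing and exact", {
  a <- binary_mask(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2), "otsu2")
  b <- binary_mask(matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2), "otsu3")
  expect_equal(intersect_masks(a, a)$values, a$values)
  empty <- binary_mask(matrix(FALSE, 2, 2))
  expect_equal(sum(intersect_masks(a, empty)$values), 0L)
  expect_equal(intersect_masks(a, b)$values, a$values & b$values)
  expect_equal(intersect_masks(a, b)$provenance, "intersection")
  expect_error(intersect_masks(a, binary_mask(matrix(TRUE, 3, 3))), "shapes differ")
})

test_that("segmentation intersects the per-phase top classes", {
  ph <- phantom1()
  seg <- segment_slice(ph$stack)
  m2 <- seg$intermediates[["2"]]$mask$values
  m3 <- seg$intermediates[["3"]]$mask$values
  expect_true(all(!seg$mask$values | m2))              # I_otsu subset of I_otsu2
  expect_true(all(!seg$mask$values | m3))
  # all phantom lesions of rule size overlap the intersection mask
  for (m in ph$truth$lesion_masks) {
    mc <- crop_to_window(m * 1, seg$window) > 0
    if (attr(m, "area") >= 15) expect_gte(sum(mc & seg$mask$values) / sum(mc), 0.5)
  }
})
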