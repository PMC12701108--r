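test_that("disk dilation is extensive and r=1 gives the 4-neighbour cross", {
  m <- matrix(FALSE, 5, 5)
  m[3, 3] <- TRUE
  d1 <- dilate_mask(m, 1)
  expect_equal(sum(d1), 5L)                            # centre + 4 neighbours
  expect_true(all(d1[cbind(c(3, 2, 4, 3, 3), c(3, 3, 3, 2, 4))]))
  expect_identical(dilate_mask(m, 0), m)
  set.seed(10)
  big <- matrix(runif(100) > 0.7, 10, 10)
  expect_true(all(dilate_mask(big, 2)[big]))           # input contained in output
  expect_error(dilate_mask(m, -1), "non-negative")
})

test_that("ring masks are disjoint annuli clipped at the frame", {
  m <- disk_mask(c(41, 41), 21, 21, 10)
  r <- ring_mask(m, 4)
  expect_false(any(r & m))
  expect_gt(sum(r), 0)
  idx <- which(r, arr.ind = TRUE)
  rad <- sqrt((idx[, 1] - 21)^2 + (idx[, 2] - 21)^2)
  expect_true(all(rad <= 15.5))
  expect_equal(sum(ring_mask(matrix(FALSE, 5, 5), 4)), 0L)
})

test_that("GLCM statistics match the hand-enumerated stripe oracle", {
  img <- matrix(c(0, 0, 1, 1), 2, 2)                   # two vertical stripes
  g <- glcm_features(img, matrix(TRUE, 2, 2), levels = 2, distances = 1, angles = 0)
  expect_equal(unname(g["contrast_d1"]), 1)
  expect_equal(unname(g["correlation_d1"]), -1)
  expect_equal(unname(g["energy_d1"]), 0.5)
  expect_equal(unname(g["homogeneity_d1"]), 0.5)
  expect_equal(unname(g["entropy_d1"]), 1)             # one bit
  expect_equal(unname(g["idm_d1"]), 0.5)
})

test_that("a constant ROI yields the degenerate GLCM values with a warning", {
  img <- matrix(0.3, 6, 6)
  expect_warning(g <- glcm_features(img, matrix(TRUE, 6, 6), distances = 1), "constant ROI")
  expect_equal(unname(g["contrast_d1"]), 0)
  expect_equal(unname(g["energy_d1"]), 1)
  expect_equal(unname(g["homogeneity_d1"]), 1)
  expect_equal(unname(g["entropy_d1"]), 0)
  expect_equal(unname(g["correlation_d1"]), 0)
})

test_that("direction-averaged GLCM features are 90-degree rotation invariant", {
  set.seed(11)
  img <- matrix(runif(100), 10, 10)
  m <- disk_mask(c(10, 10), 5, 5, 4)
  rot <- function(x) t(x)[, nrow(x):1]                 # 90-degree rotation
  g1 <- glcm_features(img, m)
  g2 <- glcm_features(rot(img), rot(m) > 0)
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("GLCM features are invariant to intensity shifts; CON is not", {
  set.seed(12)
  img <- matrix(runif(144), 12, 12)
  m <- disk_mask(c(12, 12), 6, 6, 4)
  ring <- ring_mask(m, 3)
  expect_equal(glcm_features(img, m), glcm_features(img + 5, m))
  c1 <- contrast_features(img + 0.1, m, ring)
  c2 <- contrast_features(img + 5, m, ring)
  expect_false(isTRUE(all.equal(c1$con, c2$con)))
})

test_that("ring-contrast ratios follow their defining formulas", {
  img <- matrix(0, 30, 30)
  m <- disk_mask(c(30, 30), 15, 15, 5)
  ring <- ring_mask(m, 4)
  img[m] <- 150
  img[ring] <- 50
  img <- img + matrix(rnorm(900, 0, 1e-6), 30, 30)     # avoid zero variances
  cf <- contrast_features(img, m, ring)
  expect_equal(cf$con, 0.5, tolerance = 1e-6)          # (150-50)/(150+50)

  img2 <- matrix(0, 30, 30)
  img2[m] <- 10
  img2[ring] <- 6
  set.seed(13)
  noise <- matrix(0, 30, 30)
  noise[m | ring] <- rnorm(sum(m | ring), 0, sqrt(2))
  # equal intensities give CON = 0 and C = 0
  flatimg <- matrix(5, 30, 30) + noise
  cfe <- contrast_features(flatimg, m, ring)
  expect_lt(abs(cfe$con), 0.05)
  expect_lt(cfe$c, 0.5)

  expect_error(contrast_features(matrix(0, 30, 30), m, ring), "CON undefined")
  expect_error(contrast_features(matrix(1, 30, 30), m, ring), "C undefined")
})

test_that("the default feature vector has 14 entries, 16 with extras", {
  ph <- phantom1()
  seg <- segment_slice(ph$stack)
  rois <- region_props(seg$mask$values)
  roi <- rois[[which.max(vapply(rois, `[[`, numeric(1), "area_px"))]]
  v <- extract_feature_vector(seg$phase0_cropped, roi)
  expect_length(v, 14L)
  expect_named(v, c(paste0(rep(c("contrast", "correlation", "energy", "homogeneity",
                                 "entropy", "idm"), 2), rep(c("_d1", "_d2"), each = 6)),
                    "con", "c"))
  expect_true(v[["energy_d1"]] > 0 && v[["energy_d1"]] <= 1)
  expect_true(v[["homogeneity_d1"]] > 0 && v[["homogeneity_d1"]] <= 1)
  expect_true(abs(v[["con"]]) <= 1)
  v16 <- extract_feature_vector(seg$phase0_cropped, roi, extras = TRUE)
  expect_length(v16, 16L)
  expect_identical(v, extract_feature_vector(seg$phase0_cropped, roi))  # deterministic
})
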