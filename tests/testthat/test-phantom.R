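test_that("phantom generation is bit-identical under a fixed seed", {
  a <- generate_phantom(phantom_config(seed = 3))
  b <- generate_phantom(phantom_config(seed = 3))
  expect_identical(a, b)
  c <- generate_phantom(phantom_config(seed = 4))
  expect_false(identical(a$stack$phases, c$stack$phases))
})

test_that("phantom truth respects its structural invariants", {
  ph <- phantom1()
  tr <- ph$truth
  expect_length(tr$lesion_masks, 3L)
  union <- matrix(FALSE, 256, 256)
  for (m in tr$lesion_masks) {
    expect_false(any(union & m))                        # pairwise disjoint
    union <- union | m
    expect_true(all(tr$breast_mask[m]))                 # lesions inside breast
  }
  expect_false(any(union & tr$vessel_mask))
  expect_false(any((union | tr$vessel_mask) & tr$thorax_mask))
  expect_false(any(tr$breast_mask & tr$thorax_mask))
  expect_true(all(tr$breast_mask[tr$vessel_mask]))
})

test_that("kinetic classes shape the subtraction time-courses as designed", {
  cfg <- phantom_config(n_lesions = 3L, lesion_sizes = c(30, 30, 30),
                        kinetic_classes = c("persistent", "plateau", "washout"),
                        seed = 9)
  ph <- generate_phantom(cfg)
  sub <- lapply(1:6, function(k) subtraction_image(ph$stack, k)$values)
  course <- function(m) vapply(sub, function(s) mean(s[m]), numeric(1))
  per <- course(ph$truth$lesion_masks[[1]])
  pla <- course(ph$truth$lesion_masks[[2]])
  was <- course(ph$truth$lesion_masks[[3]])
  expect_true(all(diff(per) > -0.02))                   # monotone rise (noise slack)
  expect_lt(abs(pla[6] - pla[2]), 0.03)                 # plateau holds its level
  expect_lt(was[3], was[2])                             # washout strictly decreases
  expect_lt(was[6], was[3])
})

test_that("lesions out-enhance the healthy breast tissue 95th percentile", {
  ph <- phantom1()
  tr <- ph$truth
  lesion_union <- Reduce(`|`, tr$lesion_masks)
  healthy <- tr$breast_mask & !lesion_union & !tr$vessel_mask
  for (k in 2:3) {
    s <- subtraction_image(ph$stack, k)$values
    q95 <- quantile(s[healthy], 0.95)
    for (m in tr$lesion_masks) expect_gt(mean(s[m]), q95)
  }
})

test_that("benchmark is reproducible and spans the designed size range", {
  bm <- bench3()
  bm2 <- generate_benchmark(3, seed = 5)
  expect_identical(bm, bm2)
  areas <- unlist(lapply(bench20(), function(s)
    vapply(s$truth$lesion_masks, attr, numeric(1), "area")))
  expect_gt(sum(areas < 15), 0)                         # sub-rule-size lesions exist
  expect_gt(max(areas), 40)
  kin <- unlist(lapply(bench20(), function(s)
    vapply(s$truth$lesion_masks, attr, character(1), "kinetic")))
  expect_setequal(unique(kin), c("persistent", "plateau", "washout"))
})

test_that("generated vessels are thin and highly eccentric", {
  found <- FALSE
  for (s in bench20()) {
    for (v in region_props(s$truth$vessel_mask)) {
      expect_gt(v$eccentricity, 0.95)
      found <- TRUE
    }
  }
  expect_true(found)
})

test_that("the air background stays exactly zero", {
  ph <- phantom1()
  body <- ph$truth$breast_mask | ph$truth$thorax_mask
  for (p in ph$stack$phases) expect_true(all(p[!body] == 0))
})

test_that("simulated feature clouds are balanced, shifted, seeded", {
  sim <- simulate_feature_clouds(100, 6, 4, seed = 2)
  expect_equal(as.vector(table(sim$y)), c(50, 50))
  expect_equal(dim(sim$X), c(100L, 6L))
  gap <- colMeans(sim$X[sim$y == "lesion", ]) - colMeans(sim$X[sim$y == "healthy", ])
  expect_true(all(abs(gap - 4) < 1))
  expect_identical(sim, simulate_feature_clouds(100, 6, 4, seed = 2))
})
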