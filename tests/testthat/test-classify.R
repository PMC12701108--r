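test_that("SMOTE balances classes with convex synthetic minority points", {
  set.seed(20)
  X <- matrix(rnorm(70 * 3), 70, 3)
  y <- factor(c(rep("min", 20), rep("maj", 50)))
  sm <- smote_balance(X, y, seed = 1)
  expect_equal(unname(table(sm$y)[["min"]]), 50L)
  expect_equal(unname(table(sm$y)[["maj"]]), 50L)
  expect_identical(sm$X[1:70, ], X)                    # originals preserved
  expect_equal(sum(sm$synthetic), 30L)

  # every synthetic point lies on a segment between two minority samples
  Xm <- X[y == "min", ]
  syn <- sm$X[sm$synthetic, ]
  on_segment <- function(s) {
    for (i in 1:nrow(Xm)) for (j in 1:nrow(Xm)) {
      if (i == j) next
      d <- Xm[j, ] - Xm[i, ]
      t <- sum((s - Xm[i, ]) * d) / sum(d^2)
      if (t >= -1e-9 && t <= 1 + 1e-9 &&
          sqrt(sum((Xm[i, ] + t * d - s)^2)) < 1e-8) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(syn, 1, on_segment)))

  bal <- smote_balance(X[1:40, ], factor(rep(c("a", "b"), 20)), seed = 1)
  expect_identical(bal$X, X[1:40, ])                   # balanced input unchanged
  expect_error(smote_balance(X, factor(c("a", rep("b", 69))), seed = 1), "at least 2")
})

test_that("confusion metrics follow their definitions, NA when undefined", {
  m <- confusion_metrics(tp = 12, fp = 2, tn = 10, fn = 1)
  expect_equal(m$accuracy, 22 / 25)
  expect_equal(m$sensitivity, 12 / 13)
  expect_equal(m$specificity, 10 / 12)
  expect_equal(m$precision, 12 / 14)
  perf <- confusion_metrics(10, 0, 10, 0)
  expect_true(all(unlist(perf) == 1))
  expect_equal(confusion_metrics(5, 3, 2, 0)$sensitivity, 1)   # FN = 0
  expect_true(is.na(confusion_metrics(0, 0, 5, 0)$precision))  # undefined, not 0
  expect_error(confusion_metrics(-1, 0, 0, 2), "non-negative")
})

test_that("ROC/AUC equals the Mann-Whitney ranking probability", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), factor(c("n", "n", "p", "p")), positive = "p")
  expect_equal(r$auc, 0.75)                            # 3 of 4 pairs ordered
  expect_equal(roc_auc(1:6, factor(rep(c("n", "p"), each = 3)), "p")$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), factor(rep(c("n", "p"), 5)), "p")$auc, 0.5)
  expect_error(roc_auc(1:4, factor(rep("p", 4)), "p"), "both classes")
  # the curve starts at (0,0) and ends at (1,1)
  expect_equal(unlist(r$roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc[nrow(r$roc), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
})

test_that("AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  sc <- rnorm(80)
  lb <- factor(sample(c("n", "p"), 80, replace = TRUE))
  ours <- roc_auc(sc, lb, "p")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c("n", "p"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref)
})

test_that("exact and mid-p McNemar match the binomial enumeration", {
  d <- make_discordant(2, 3)
  ex <- mcnemar_test(d$y, d$a, d$b, "exact", "a.better")
  mp <- mcnemar_test(d$y, d$a, d$b, "midp", "a.better")
  expect_equal(ex$p, 0.8125)                           # 26/32
  expect_equal(mp$p, 0.65625)                          # 21/32
  expect_equal(c(ex$b, ex$c), c(2L, 3L))

  d2 <- make_discordant(5, 4)
  expect_equal(mcnemar_test(d2$y, d2$a, d2$b, "exact", "a.better")$p, 0.5)
  expect_equal(mcnemar_test(d2$y, d2$a, d2$b, "midp", "a.better")$p, 193 / 512)

  # brute force over all 2^n discordance patterns, n up to 12
  for (bc in list(c(1, 2), c(4, 2), c(5, 4), c(7, 5), c(2, 10))) {
    d3 <- make_discordant(bc[1], bc[2])
    got <- mcnemar_test(d3$y, d3$a, d3$b, "exact", "a.better")$p
    expect_equal(got, enum_mcnemar_p(bc[1], bc[2]))
    midp <- mcnemar_test(d3$y, d3$a, d3$b, "midp", "a.better")$p
    expect_lte(midp, got)                              # mid-p never exceeds exact
    expect_gt(midp, 0)
  }
})

test_that("McNemar decision and degenerate conventions hold", {
  d <- make_discordant(2, 3)
  ex <- mcnemar_test(d$y, d$a, d$b, "exact", "a.better")
  expect_equal(ex$h, 0L)                               # p >= 0.05 keeps the null
  big <- make_discordant(12, 0)
  expect_equal(mcnemar_test(big$y, big$a, big$b, "exact", "a.better")$h, 1L)
  expect_warning(deg <- mcnemar_test(c(1, 1), c(1, 1), c(1, 1)), "no discordant")
  expect_equal(deg$p, 1)
  expect_equal(deg$h, 0L)
  two <- mcnemar_test(d$y, d$a, d$b, "exact", "two.sided")
  expect_true(two$p >= ex$p - 1e-12 || two$p <= 1)
  asym <- mcnemar_test(d$y, d$a, d$b, "asymptotic", "two.sided")
  expect_true(asym$p > 0 && asym$p <= 1)
})

test_that("the FFBPN recovers separable clouds and reports 65/15/20 splits", {
  sim <- simulate_feature_clouds(200, 6, 4, seed = 22)
  ev <- train_eval_ffbpn(sim$X, sim$y, positive = "lesion", hidden_n = 6,
                         repeats = 2, seed = 1)
  expect_s3_class(ev, "cad_eval")
  expect_true(all(ev$per_repeat$accuracy >= 0.9))
  # split arithmetic for n = 200: 130 train / 30 validation / 40 test
  counts <- table(dcecad:::.local_seed(1, dcecad:::.split_65_15_20(sim$y)))
  expect_equal(as.integer(counts[c("train", "val", "test")]), c(130L, 30L, 40L))
  # two output units, prediction by the larger one
  expect_setequal(levels(ev$predictions$pred), c("healthy", "lesion"))
})

test_that("SVM cross-validation predicts every sample exactly once", {
  sim <- simulate_feature_clouds(150, 5, 4, seed = 23)
  ev <- train_eval_svm(sim$X, sim$y, positive = "lesion", folds = 5, seed = 2)
  expect_equal(sort(ev$predictions$idx), 1:150)
  expect_gte(ev$auc, 0.95)
  expect_gte(ev$metrics$sensitivity, 0.9)
})

test_that("CV metrics are invariant to the order samples arrive in", {
  sim <- simulate_feature_clouds(120, 5, 3, seed = 24)
  e1 <- train_eval_svm(sim$X, sim$y, positive = "lesion", seed = 7)
  set.seed(25)
  perm <- sample(120)
  e2 <- train_eval_svm(sim$X[perm, ], sim$y[perm], positive = "lesion", seed = 7)
  expect_equal(e1$metrics, e2$metrics)
  expect_equal(e1$auc, e2$auc)
})
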