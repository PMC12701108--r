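test_that("ReliefF rewards the class-aligned feature and zeroes noise", {
  set.seed(14)
  n <- 200
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(info = as.numeric(y == "b") + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 9), n, 9))
  colnames(X)[2:10] <- paste0("noise", 1:9)
  w <- relieff_weights(X, y, k = 10)
  expect_equal(names(which.max(w)), "info")
  expect_true(all(w <= 1 & w >= -1))

  set.seed(15)
  Xn <- matrix(rnorm(500 * 5), 500, 5)
  yn <- factor(rep(c("a", "b"), 250))
  wn <- relieff_weights(Xn, yn, k = 10)
  expect_true(all(abs(wn) < 0.05))                     # pure noise near zero
})

test_that("ReliefF weights are symmetric for duplicates and scale invariant", {
  set.seed(16)
  n <- 120
  y <- factor(rep(c("a", "b"), each = n / 2))
  base <- cbind(f1 = as.numeric(y == "b") + rnorm(n, 0, 0.3), f2 = rnorm(n))
  X <- cbind(base, dup = base[, "f1"])
  w <- relieff_weights(X, y, k = 8)
  expect_equal(w[["f1"]], w[["dup"]])
  Xs <- X
  Xs[, "f1"] <- Xs[, "f1"] * 1000 + 7                  # rescaled copy
  Xs[, "dup"] <- Xs[, "dup"] * 1000 + 7
  expect_equal(relieff_weights(Xs, y, k = 8), w, tolerance = 1e-10)
})

test_that("ReliefF validates classes and neighbour counts", {
  X <- matrix(rnorm(40), 20, 2)
  expect_error(relieff_weights(X, rep("a", 20)), "two classes")
  expect_error(relieff_weights(X, rep(c("a", "b"), 10), k = 10), "too large")
})

test_that("backward elimination reaches the exhaustive-search optimum", {
  set.seed(17)
  n <- 90
  y <- factor(rep(c("a", "b"), length.out = n))
  X <- cbind(x1 = (as.numeric(y == "b") + rnorm(n, 0, 0.15)) / 2,
             x2 = (-as.numeric(y == "b") + rnorm(n, 0, 0.15)) / 2,
             matrix(rnorm(n * 4), n, 4))
  colnames(X)[3:6] <- paste0("n", 1:4)
  loo_1nn <- function(Xs, yy) {                        # deterministic criterion
    D <- as.matrix(dist(Xs))
    diag(D) <- Inf
    mean(yy[apply(D, 1, which.min)] != yy)
  }
  sel <- sequential_backward_select(X, y, criterion = loo_1nn)
  best <- Inf
  Xs <- dcecad:::.minmax_scale(X)
  for (k in 1:6) for (s in utils::combn(6, k, simplify = FALSE))
    best <- min(best, loo_1nn(Xs[, s, drop = FALSE], y))
  expect_equal(sel$criterion, best)                    # greedy achieves the optimum
  expect_true(all(sel$selected %in% c("x1", "x2")))    # no noise feature survives
})

test_that("elimination drops redundant duplicates and respects the fixed point", {
  set.seed(18)
  n <- 80
  y <- factor(rep(c("a", "b"), each = n / 2))
  f <- as.numeric(y == "b") + rnorm(n, 0, 0.2)
  X <- cbind(a = f, b = rnorm(n), dup = f)
  crit <- function(Xs, yy) {
    D <- as.matrix(dist(Xs))
    diag(D) <- Inf
    mean(yy[apply(D, 1, which.min)] != yy)
  }
  sel <- sequential_backward_select(X, y, criterion = crit)
  expect_lt(sum(sel$selected %in% c("a", "dup")), 2L)  # at most one duplicate survives

  # criterion that strictly worsens under any removal: input is the fixed point
  worsen <- function(Xs, yy) 1 - ncol(Xs) / 100
  sel2 <- sequential_backward_select(X, y, criterion = worsen)
  expect_equal(sel2$selected, colnames(X))
  expect_equal(sel2$trace$step, 0L)
})

test_that("the default wrapped-SVM criterion selects on phantom-like data", {
  sim <- simulate_feature_clouds(80, 4, 4, seed = 19)
  sel <- sequential_backward_select(sim$X, sim$y, seed = 3)
  expect_gte(length(sel$selected), 1L)
  expect_lte(sel$criterion, 0.1)
})
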