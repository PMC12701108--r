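# Internal feed-forward backpropagation network: one hidden layer of tanh
# units, two tanh output units (prediction = larger output), mean-squared
# error loss, trained by full-batch nonlinear conjugate gradient in short
# cycles with early stopping on a validation split.

.mlp_unpack <- function(w, p, h) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- w[i + seq_len(h)]; i <- i + h
  W2 <- matrix(w[i + seq_len(h * 2L)], h, 2L); i <- i + h * 2L
  b2 <- w[i + seq_len(2L)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.mlp_forward <- function(par, X) {
  Z <- tanh(sweep(X %*% par$W1, 2L, par$b1, `+`))
  Y <- tanh(sweep(Z %*% par$W2, 2L, par$b2, `+`))
  list(Z = Z, Y = Y)
}

.mlp_loss <- function(w, X, Tm, np, nh) {
  par <- .mlp_unpack(w, np, nh)
  Y <- .mlp_forward(par, X)$Y
  mean((Y - Tm)^2)
}

.mlp_grad <- function(w, X, Tm, np, nh) {
  par <- .mlp_unpack(w, np, nh)
  fw <- .mlp_forward(par, X)
  n <- nrow(X)
  dY <- 2 * (fw$Y - Tm) / (n * 2L) * (1 - fw$Y^2)
  dW2 <- crossprod(fw$Z, dY)
  db2 <- colSums(dY)
  dZ <- (dY %*% t(par$W2)) * (1 - fw$Z^2)
  dW1 <- crossprod(X, dZ)
  db1 <- colSums(dZ)
  c(as.vector(dW1), db1, as.vector(dW2), db2)
}

# Train with validation-based early stopping: conjugate-gradient cycles of
# `cycle` iterations; stop after `patience` cycles without validation
# improvement or `max_epochs` total iterations. Returns the best-validation
# weights.
.mlp_train <- function(X_tr, T_tr, X_val, T_val, hidden_n,
                       max_epochs = 1000L, patience = 6L, cycle = 25L) {
  p <- ncol(X_tr); h <- hidden_n
  w <- runif(p * h + h + h * 2L + 2L, -0.5, 0.5) / sqrt(p)
  best_w <- w
  best_val <- .mlp_loss(w, X_val, T_val, p, h)
  fails <- 0L
  used <- 0L
  while (used < max_epochs && fails < patience) {
    opt <- stats::optim(w, fn = .mlp_loss, gr = .mlp_grad, X = X_tr, Tm = T_tr,
                        np = p, nh = h, method = "CG",
                        control = list(maxit = cycle))
    w <- opt$par
    used <- used + cycle
    val <- .mlp_loss(w, X_val, T_val, p, h)
    if (val < best_val - 1e-9) {
      best_val <- val
      best_w <- w
      fails <- 0L
    } else fails <- fails + 1L
  }
  structure(list(w = best_w, p = p, h = h, val_mse = best_val, iterations = used),
            class = "dcecad_mlp")
}

.mlp_predict <- function(fit, X) {
  par <- .mlp_unpack(fit$w, fit$p, fit$h)
  Y <- .mlp_forward(par, X)$Y
  list(class_index = max.col(Y), score = Y[, 2L] - Y[, 1L])
}
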