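# Second classification stage and evaluation machinery: SMOTE balancing,
# the feed-forward network and the Gaussian-kernel SVM, confusion metrics,
# ROC/AUC, and exact-conditional / mid-p McNemar classifier comparison.

#' SMOTE minority oversampling
#'
#' Balances a two-class dataset by synthesizing minority samples on the
#' segments between each minority sample and one of its `k` nearest
#' minority neighbours (Euclidean), until class counts are equal. The
#' original samples are preserved and returned first.
#'
#' @param X numeric matrix or data.frame (samples x features).
#' @param y two-class labels.
#' @param k minority neighbours to interpolate with (default 5; reduced if
#'   the minority class is smaller).
#' @param seed RNG seed.
#' @return list(X, y, synthetic): augmented data and a logical vector
#'   marking the synthesized rows.
#' @export
smote_balance <- function(X, y, k = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2L) stop("SMOTE expects exactly two classes")
  tab <- table(droplevels(y))
  if (tab[1L] == tab[2L])
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  minority <- names(tab)[which.min(tab)]
  mi <- which(y == minority)
  if (length(mi) < 2L) stop("SMOTE needs at least 2 minority samples")
  need <- max(tab) - min(tab)
  k_eff <- min(k, length(mi) - 1L)
  Xm <- X[mi, , drop = FALSE]
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k_eff)]))
  .local_seed(seed, {
    parent <- rep_len(seq_along(mi), need)             # cycle through minority samples
    pick <- nn[cbind(parent, sample.int(k_eff, need, replace = TRUE))]
    u <- runif(need)
    Xnew <- Xm[parent, , drop = FALSE] + u * (Xm[pick, , drop = FALSE] - Xm[parent, , drop = FALSE])
    list(X = rbind(X, Xnew),
         y = factor(c(as.character(y), rep(minority, need)), levels = levels(y)),
         synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, need)))
  })
}

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/n`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)`. A metric with a zero denominator
#' is reported as `NA` (undefined), not 0.
#'
#' @param tp,fp,tn,fn non-negative counts with `tp+fp+tn+fn > 0`.
#' @return named list(accuracy, sensitivity, specificity, precision).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0) || sum(counts) == 0) stop("counts must be non-negative with n > 0")
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  list(accuracy = (tp + tn) / sum(counts),
       sensitivity = rat(tp, tp + fn),
       specificity = rat(tn, tn + fp),
       precision = rat(tp, tp + fp))
}

.count_confusion <- function(truth, pred, positive) {
  list(tp = sum(pred == positive & truth == positive),
       fp = sum(pred == positive & truth != positive),
       tn = sum(pred != positive & truth != positive),
       fn = sum(pred != positive & truth == positive))
}

#' Empirical ROC curve and AUC
#'
#' ROC points over all distinct score thresholds; the area under the curve
#' is computed by the trapezoidal rule and equals the Mann-Whitney
#' probability that a random positive outranks a random negative, counting
#' ties as 1/2.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels class labels.
#' @param positive positive class (default: the larger level).
#' @return list(roc: data.frame(threshold, fpr, tpr), auc).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  if (is.null(positive)) positive <- levels(labels)[nlevels(labels)]
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("ROC undefined: both classes must be present")
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  thr <- unique(scores[ord])
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n0, numeric(1))
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- (sum(rank(scores)[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = roc, auc = auc)
}

#' McNemar comparison of two classifiers
#'
#' Compares paired predictions through the discordant counts `b` (A right,
#' B wrong) and `c` (A wrong, B right), which under the null of equal
#' performance are Binomial(b+c, 1/2). Variants: `exact` (exact-conditional
#' binomial tail), `midp` (tail beyond the observed count plus half its
#' point mass), `asymptotic` (normal approximation). With
#' `alternative = "a.better"` the one-sided tail `P(X >= b)` is reported
#' (small when `b` is large, i.e. when A outperforms B).
#'
#' @param y_true true labels.
#' @param pred_a,pred_b predictions of classifiers A and B.
#' @param variant "exact" (default), "midp" or "asymptotic".
#' @param alternative "two.sided" (default) or "a.better".
#' @param alpha significance level (default 0.05).
#' @return list(h: 1 iff p < alpha, p, b, c, variant, alternative). With
#'   `b + c = 0` the test is degenerate: p = 1, h = 0, with a warning.
#' @export
mcnemar_test <- function(y_true, pred_a, pred_b,
                         variant = c("exact", "midp", "asymptotic"),
                         alternative = c("two.sided", "a.better"),
                         alpha = 0.05) {
  variant <- match.arg(variant)
  alternative <- match.arg(alternative)
  if (length(y_true) != length(pred_a) || length(y_true) != length(pred_b))
    stop("prediction vectors must match y_true in length")
  b <- sum(pred_a == y_true & pred_b != y_true)
  c_ <- sum(pred_a != y_true & pred_b == y_true)
  n <- b + c_
  if (n == 0L) {
    warning("no discordant pairs: McNemar test degenerate (p = 1)")
    return(list(h = 0L, p = 1, b = b, c = c_, variant = variant, alternative = alternative))
  }
  upper <- function(x) pbinom(x - 1L, n, 0.5, lower.tail = FALSE)   # P(X >= x)
  p <- switch(variant,
    exact = if (alternative == "a.better") upper(b)
            else min(1, 2 * min(upper(max(b, c_)), pbinom(min(b, c_), n, 0.5))),
    midp = if (alternative == "a.better") upper(b + 1L) + 0.5 * dbinom(b, n, 0.5)
           else {
             m <- max(b, c_)
             min(1, 2 * (upper(m + 1L) + 0.5 * dbinom(m, n, 0.5)))
           },
    asymptotic = {
      z <- (b - c_) / sqrt(n)
      if (alternative == "a.better") pnorm(z, lower.tail = FALSE) else 2 * pnorm(-abs(z))
    })
  list(h = as.integer(p < alpha), p = p, b = b, c = c_,
       variant = variant, alternative = alternative)
}

.metrics_row <- function(truth, pred, positive) {
  cm <- .count_confusion(truth, pred, positive)
  mt <- confusion_metrics(cm$tp, cm$fp, cm$tn, cm$fn)
  data.frame(accuracy = mt$accuracy, sensitivity = mt$sensitivity,
             specificity = mt$specificity, precision = mt$precision,
             tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn)
}

.new_cad_eval <- function(classifier, predictions, positive, per_repeat = NULL) {
  pooled <- .metrics_row(predictions$truth, predictions$pred, positive)
  ra <- tryCatch(roc_auc(predictions$score, predictions$truth, positive),
                 error = function(e) list(roc = NULL, auc = NA_real_))
  structure(list(
    classifier = classifier, positive = positive,
    metrics = pooled[, 1:4], counts = pooled[, 5:8],
    per_repeat = per_repeat,
    mean = if (!is.null(per_repeat)) colMeans(per_repeat[, 1:4], na.rm = TRUE),
    sd = if (!is.null(per_repeat)) apply(per_repeat[, 1:4], 2L, sd, na.rm = TRUE),
    roc = ra$roc, auc = ra$auc, predictions = predictions), class = "cad_eval")
}

#' @export
print.cad_eval <- function(x, digits = 3, ...) {
  cat(sprintf("<cad_eval> %s (positive class: %s)\n", x$classifier, x$positive))
  m <- unlist(x$metrics)
  cat(sprintf("  pooled: accuracy %.3f | sensitivity %.3f | specificity %.3f | precision %.3f\n",
              m[1L], m[2L], m[3L], m[4L]))
  if (!is.null(x$per_repeat))
    cat(sprintf("  over %d repeats: accuracy %.3f +/- %.3f\n",
                nrow(x$per_repeat), x$mean[["accuracy"]], x$sd[["accuracy"]]))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.3f\n", x$auc))
  invisible(x)
}

# stratified 65/15/20 split (train/validation/test), per class
.split_65_15_20 <- function(y) {
  y <- as.factor(y)
  role <- character(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    ncl <- length(idx)
    n_tr <- round(0.65 * ncl); n_val <- round(0.15 * ncl)
    role[idx[seq_len(n_tr)]] <- "train"
    role[idx[n_tr + seq_len(n_val)]] <- "val"
    role[idx[(n_tr + n_val + 1L):ncl]] <- "test"
  }
  role
}

#' Train and evaluate the feed-forward backpropagation network
#'
#' One hidden layer of `hidden_n` tanh units and two tanh output units
#' (prediction = larger output), mean-squared-error loss, conjugate-
#' gradient training with early stopping on a validation split. Each
#' repeat draws a fresh stratified 65/15/20 train/validation/test split;
#' test-set metrics are reported per repeat and as mean +/- sd, with
#' pooled held-out predictions for ROC/AUC and McNemar comparisons.
#'
#' @param X numeric matrix or data.frame (samples x features).
#' @param y two-class labels.
#' @param positive positive ("lesion") class; default: second factor level.
#' @param hidden_n hidden units (default 6; the companion setting is 10).
#' @param repeats independent split/train repeats (default 5).
#' @param seed master seed.
#' @param max_epochs,patience training budget and early-stopping patience.
#' @return a `cad_eval` object.
#' @export
train_eval_ffbpn <- function(X, y, positive = NULL, hidden_n = 6L, repeats = 5L,
                             seed = 1L, max_epochs = 1000L, patience = 6L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("FFBPN evaluation expects two classes")
  if (is.null(positive)) positive <- levels(y)[2L]
  neg <- setdiff(levels(y), positive)
  per <- NULL
  preds <- data.frame()
  for (r in seq_len(repeats)) {
    .local_seed(.derive_seed(seed, r), {
      role <- .split_65_15_20(y)
      lo <- apply(X[role == "train", , drop = FALSE], 2L, min)
      hi <- apply(X[role == "train", , drop = FALSE], 2L, max)
      Xs <- sweep(sweep(X, 2L, lo, `-`), 2L, pmax(hi - lo, .Machine$double.eps), `/`)
      Tmat <- cbind(ifelse(y == neg, 1, -1), ifelse(y == positive, 1, -1))
      fit <- .mlp_train(Xs[role == "train", , drop = FALSE], Tmat[role == "train", ],
                        Xs[role == "val", , drop = FALSE], Tmat[role == "val", ],
                        hidden_n, max_epochs = max_epochs, patience = patience)
      te <- which(role == "test")
      pr <- .mlp_predict(fit, Xs[te, , drop = FALSE])
      pred <- factor(c(neg, positive)[pr$class_index], levels = levels(y))
      per <- rbind(per, cbind(repeat_ = r, .metrics_row(y[te], pred, positive)))
      preds <- rbind(preds, data.frame(idx = te, repeat_ = r, truth = y[te],
                                       pred = pred, score = pr$score))
    })
  }
  .new_cad_eval(paste0("ffbpn_", hidden_n), preds, positive,
                per_repeat = per[, -1L, drop = FALSE])
}

#' Train and evaluate the Gaussian-kernel SVM with SMOTE
#'
#' Stratified k-fold cross-validation; inside each training fold the
#' classes are SMOTE-balanced (synthetic samples never reach a validation
#' fold) and the kernel coefficient gamma and cost are tuned by an inner
#' 3-fold grid search; pooled out-of-fold predictions yield the confusion
#' metrics and the ROC/AUC.
#'
#' @param X numeric matrix or data.frame (samples x features).
#' @param y two-class labels.
#' @param positive positive class; default: second factor level.
#' @param folds CV folds (default 5).
#' @param seed fold/SMOTE seed.
#' @param smote apply SMOTE inside training folds (default TRUE).
#' @param gamma_mult,cost grids for the inner tuning, relative to the
#'   1/n_features default gamma.
#' @return a `cad_eval` object.
#' @export
train_eval_svm <- function(X, y, positive = NULL, folds = 5L, seed = 1L, smote = TRUE,
                           gamma_mult = c(0.25, 1, 4), cost = c(1, 10)) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("SVM evaluation expects two classes")
  if (is.null(positive)) positive <- levels(y)[2L]
  fid <- .stratified_folds(y, folds, seed, X = X)
  if (any(vapply(seq_len(folds), function(f) nlevels(droplevels(y[fid == f])) < 2L, logical(1))))
    stop("stratification failed: a fold holds a single class")
  gamma0 <- 1 / ncol(X)
  preds <- data.frame()
  for (f in seq_len(folds)) {
    tr <- which(fid != f); te <- which(fid == f)
    lo <- apply(X[tr, , drop = FALSE], 2L, min)
    hi <- apply(X[tr, , drop = FALSE], 2L, max)
    Xs <- sweep(sweep(X, 2L, lo, `-`), 2L, pmax(hi - lo, .Machine$double.eps), `/`)
    Xtr <- Xs[tr, , drop = FALSE]; ytr <- y[tr]
    # canonical row order inside the training fold keeps SMOTE and the SVM
    # fit invariant to the order the samples arrived in
    ord <- do.call(order, as.data.frame(Xtr))
    Xtr <- Xtr[ord, , drop = FALSE]; ytr <- ytr[ord]
    if (smote) {
      sm <- smote_balance(Xtr, ytr, seed = .derive_seed(seed, f))
      Xtr <- sm$X; ytr <- sm$y
    }
    # inner 3-fold tuning of gamma and cost
    inner <- .stratified_folds(ytr, 3L, .derive_seed(seed, 100L + f))
    grid <- expand.grid(gamma = gamma0 * gamma_mult, cost = cost)
    err <- vapply(seq_len(nrow(grid)), function(g) {
      wrong <- 0L
      for (i in 1:3) {
        itr <- inner != i
        fit <- e1071::svm(Xtr[itr, , drop = FALSE], ytr[itr], kernel = "radial",
                          gamma = grid$gamma[g], cost = grid$cost[g], scale = FALSE)
        wrong <- wrong + sum(predict(fit, Xtr[!itr, , drop = FALSE]) != ytr[!itr])
      }
      wrong / length(ytr)
    }, numeric(1))
    best <- grid[which.min(err), ]
    fit <- e1071::svm(Xtr, ytr, kernel = "radial", gamma = best$gamma, cost = best$cost,
                      scale = FALSE, decision.values = TRUE)
    pr <- predict(fit, Xs[te, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # orient decision values so larger = positive class
    first <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
    score <- if (first == positive) dv[, 1L] else -dv[, 1L]
    preds <- rbind(preds, data.frame(idx = te, fold = f, truth = y[te],
                                     pred = factor(as.character(pr), levels = levels(y)),
                                     score = score))
  }
  preds <- preds[order(preds$idx), ]
  rownames(preds) <- NULL
  .new_cad_eval("svm", preds, positive)
}
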