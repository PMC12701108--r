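# Feature selection: ReliefF neighbour-based weighting (k nearest hits and
# misses per sample, Manhattan distance on min-max-scaled features) and
# greedy sequential backward elimination wrapped around a cross-validated
# classifier with the misclassification rate as criterion.

.minmax_scale <- function(X) {
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  rng <- pmax(hi - lo, .Machine$double.eps)
  sweep(sweep(X, 2L, lo, `-`), 2L, rng, `/`)
}

#' ReliefF feature weights
#'
#' Iterates over every sample (m = n); for each, finds its `k` nearest
#' same-class neighbours (hits) and `k` nearest neighbours in each other
#' class (misses) by Manhattan distance on min-max-scaled features. A
#' feature's weight is decreased by its mean absolute difference to hits
#' and increased by its (class-prior-weighted) mean absolute difference to
#' misses, so features separating classes near decision boundaries score
#' high. Weights lie in `[-1, 1]`.
#'
#' @param X numeric matrix or data.frame (samples x features).
#' @param y class labels (factor or vector), at least two classes.
#' @param k neighbours per class (default 10); must be smaller than every
#'   class count.
#' @return named numeric weights, one per feature.
#' @export
relieff_weights <- function(X, y, k = 10L) {
  X <- as.matrix(X)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("ReliefF needs at least two classes")
  y <- droplevels(y)
  tab <- table(y)
  if (any(tab <= k)) stop("k = ", k, " too large for class counts (", paste(tab, collapse = ", "), ")")
  n <- nrow(X); p <- ncol(X)
  Xs <- .minmax_scale(X)
  prior <- tab / n
  D <- as.matrix(dist(Xs, method = "manhattan"))
  diag(D) <- Inf
  W <- numeric(p)
  for (i in seq_len(n)) {
    ci <- y[i]
    hits <- which(y == ci)
    hits <- hits[order(D[i, hits])][seq_len(k)]
    dh <- colMeans(abs(sweep(Xs[hits, , drop = FALSE], 2L, Xs[i, ], `-`)))
    dm <- numeric(p)
    for (cm in levels(y)[levels(y) != ci]) {
      miss <- which(y == cm)
      miss <- miss[order(D[i, miss])][seq_len(k)]
      w_c <- prior[[cm]] / (1 - prior[[ci]])
      dm <- dm + w_c * colMeans(abs(sweep(Xs[miss, , drop = FALSE], 2L, Xs[i, ], `-`)))
    }
    W <- W + (dm - dh) / n
  }
  names(W) <- colnames(X)
  W
}

# Stratified fold assignment, deterministic given seed. When X is supplied
# the within-class order is canonicalized by a content key first, which
# makes the assignment invariant to the row order of the input (up to
# exactly duplicated rows).
.stratified_folds <- function(y, folds, seed, X = NULL) {
  y <- as.factor(y)
  .local_seed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (!is.null(X)) {
        key <- do.call(order, as.data.frame(X[idx, , drop = FALSE]))
        idx <- idx[key]
        f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
      } else {
        f[sample(idx)] <- rep_len(seq_len(folds), length(idx))
      }
    }
    f
  })
}

# default wrapped criterion: Gaussian-kernel SVM, fixed hyperparameters,
# stratified k-fold CV misclassification rate
.svm_cv_criterion <- function(folds = 5L, seed = 1L) {
  function(X, y) {
    X <- as.matrix(X); y <- as.factor(y)
    fid <- .stratified_folds(y, folds, seed)
    wrong <- 0L
    for (f in seq_len(folds)) {
      tr <- fid != f; te <- !tr
      fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial", scale = FALSE)
      wrong <- wrong + sum(predict(fit, X[te, , drop = FALSE]) != y[te])
    }
    wrong / length(y)
  }
}

#' Sequential backward feature elimination
#'
#' Greedy backward search: starting from the full feature set, at each
#' iteration the single feature whose removal most decreases the criterion
#' (cross-validated misclassification rate of the wrapped classifier) is
#' removed; the search stops when no removal strictly decreases the
#' criterion, or one feature remains. Features are scaled to unit range
#' before the wrapped classifier sees them.
#'
#' @param X numeric matrix or data.frame (samples x features), >= 2 columns.
#' @param y class labels.
#' @param criterion function(X_subset, y) -> misclassification rate; the
#'   default wraps a Gaussian-kernel SVM with fixed hyperparameters in
#'   stratified 5-fold CV with fold assignment fixed by `seed`.
#' @param folds,seed CV folds and fold seed for the default criterion.
#' @return list(selected: surviving feature names in original order,
#'   criterion: final criterion value, trace: data.frame of the
#'   elimination path).
#' @export
sequential_backward_select <- function(X, y, criterion = NULL, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two features")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (is.null(criterion)) criterion <- .svm_cv_criterion(folds, seed)
  Xs <- .minmax_scale(X)
  current <- colnames(X)
  cur_val <- criterion(Xs[, current, drop = FALSE], y)
  trace <- data.frame(step = 0L, removed = NA_character_, criterion = cur_val,
                      n_features = length(current), stringsAsFactors = FALSE)
  step <- 0L
  while (length(current) > 1L) {
    vals <- vapply(current, function(fname) {
      criterion(Xs[, setdiff(current, fname), drop = FALSE], y)
    }, numeric(1))
    best <- which.min(vals)
    if (vals[best] > cur_val) break                   # every removal hurts: stop
    step <- step + 1L
    removed <- current[best]
    current <- setdiff(current, removed)
    cur_val <- unname(vals[best])
    trace <- rbind(trace, data.frame(step = step, removed = removed,
                                     criterion = cur_val, n_features = length(current),
                                     stringsAsFactors = FALSE))
  }
  list(selected = current, criterion = cur_val, trace = trace)
}
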