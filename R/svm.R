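#' Train a linear multiclass SVM (one-vs-one)
#'
#' L2-regularised linear SVM with L1 hinge loss, solved by dual coordinate
#' descent; multiclass handled one-vs-one with majority voting (vote ties
#' broken to the earlier class level, deterministically). `C = 1` is the
#' conventional default; no kernel.
#'
#' Features should already be scaled (see [smooth_and_scale()] with
#' `zscore_by_train`); the solver itself does no scaling.
#'
#' @param x Feature matrix (observations x features).
#' @param y Class labels (coerced to factor).
#' @param C Regularisation constant.
#' @param max_epochs,tol Solver controls.
#' @param seed Integer seed for the solver's coordinate shuffling.
#' @return An object of class `linear_svm`: list with `levels` and `weights`
#'   (one column per class pair, last row = bias).
#' @export
svm_train <- function(x, y, C = 1, max_epochs = 300, tol = 1e-4, seed = 0) {
  x <- as.matrix(x)
  y <- factor(y)
  lv <- levels(y)
  if (length(lv) < 2) stop("need at least 2 classes")
  pairs <- utils::combn(length(lv), 2)
  W <- matrix(0, ncol(x) + 1, ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    a <- pairs[1, p]; b <- pairs[2, p]
    sel <- y == lv[a] | y == lv[b]
    yy <- ifelse(y[sel] == lv[a], 1, -1)
    W[, p] <- svm_dcd_fit(x[sel, , drop = FALSE], yy, C, max_epochs, tol,
                          as.integer(seed) + p)
  }
  structure(list(levels = lv, pairs = pairs, weights = W),
            class = "linear_svm")
}

#' Predict classes from a linear SVM
#'
#' @param model A `linear_svm`.
#' @param x Feature matrix (scaled like the training data).
#' @return Factor of predicted classes.
#' @export
svm_predict <- function(model, x) {
  x <- as.matrix(x)
  scores <- cbind(x, 1) %*% model$weights
  K <- length(model$levels)
  votes <- matrix(0L, nrow(x), K)
  for (p in seq_len(ncol(model$pairs))) {
    a <- model$pairs[1, p]; b <- model$pairs[2, p]
    pos <- scores[, p] >= 0
    votes[, a] <- votes[, a] + pos
    votes[, b] <- votes[, b] + !pos
  }
  factor(model$levels[max.col(votes, ties.method = "first")],
         levels = model$levels)
}

# Stratified fold assignment: each class's trials spread over n_folds.
# Errors if a class has fewer trials than folds (a fold would miss it).
stratified_folds <- function(y, n_folds) {
  y <- factor(y)
  if (any(table(y) < n_folds)) {
    stop("need at least `n_folds` trials per class for stratified CV")
  }
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  folds
}

# One stratified cross-validation pass: train-only z-scoring, OvO linear SVM.
# Returns the K x K confusion matrix of counts (true x predicted).
decode_cv_once <- function(x, y, n_folds, C = 1, shuffle = FALSE) {
  y <- factor(y)
  if (shuffle) y <- sample(y)
  folds <- stratified_folds(y, n_folds)
  K <- nlevels(y)
  conf <- matrix(0, K, K, dimnames = list(levels(y), levels(y)))
  for (f in seq_len(n_folds)) {
    tr <- which(folds != f); te <- which(folds == f)
    xs <- smooth_and_scale(x, "zscore_by_train", train_idx = tr)
    m <- svm_train(xs[tr, , drop = FALSE], y[tr], C = C,
                   seed = sample.int(.Machine$integer.max, 1))
    pred <- svm_predict(m, xs[te, , drop = FALSE])
    conf <- conf + table(factor(y[te], levels(y)), factor(pred, levels(y)))
  }
  conf
}

#' Cross-validated SVM decoding with resampling and a shuffled-label null
#'
#' Runs stratified `n_folds`-fold cross-validation `n_resamples` times (new
#' fold splits each time; if `draw` is supplied, a new pseudotrial draw each
#' time), with train-only z-scoring inside every fold. The shuffled-label
#' null repeats the identical procedure on permuted labels.
#'
#' @param features Observations x features matrix (ignored if `draw` given).
#' @param labels Class labels (ignored if `draw` given).
#' @param n_folds Folds (default 10).
#' @param n_resamples Resamples (default 1000).
#' @param n_shuffles Shuffled-label resamples for the null (default 100).
#' @param C SVM regularisation constant.
#' @param seed Integer seed.
#' @param draw Optional `function()` returning `list(x, y)`; called afresh for
#'   every resample and shuffle (pseudopopulation redraws).
#' @return An object of class `decode_result`: list with `accuracy` (mean, %),
#'   `accuracies` (per resample, %), `confusion` (true x predicted, averaged
#'   over folds and resamples), `null_accuracies` (%), `null_p99` (%),
#'   `n_folds`, `n_resamples`.
#' @export
svm_decode <- function(features = NULL, labels = NULL, n_folds = 10,
                       n_resamples = 1000, n_shuffles = 100, C = 1,
                       seed = 1, draw = NULL) {
  set.seed(seed)
  if (is.null(draw)) {
    stopifnot(!is.null(features), !is.null(labels))
    fx <- as.matrix(features); fy <- labels
    draw <- function() list(x = fx, y = fy)
  }
  run <- function(n, shuffle) {
    acc <- numeric(n); conf_sum <- NULL
    for (i in seq_len(n)) {
      dd <- draw()
      conf <- decode_cv_once(dd$x, dd$y, n_folds, C = C, shuffle = shuffle)
      acc[i] <- 100 * sum(diag(conf)) / sum(conf)
      conf_sum <- if (is.null(conf_sum)) conf else conf_sum + conf
    }
    list(acc = acc, conf = conf_sum / n)
  }
  true <- run(n_resamples, shuffle = FALSE)
  null <- if (n_shuffles > 0) run(n_shuffles, shuffle = TRUE) else
    list(acc = numeric(0), conf = NULL)
  structure(list(
    accuracy = mean(true$acc),
    accuracies = true$acc,
    confusion = true$conf,
    null_accuracies = null$acc,
    null_p99 = if (length(null$acc)) stats::quantile(null$acc, 0.99,
                                                     names = FALSE) else NA,
    n_folds = n_folds, n_resamples = n_resamples
  ), class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("decode_result: %.2f%% accuracy (%d-fold CV, %d resamples)\n",
              x$accuracy, x$n_folds, x$n_resamples))
  if (length(x$null_accuracies)) {
    cat(sprintf("  shuffled-label null: mean %.2f%%, 99th pct %.2f%%\n",
                mean(x$null_accuracies), x$null_p99))
  }
  invisible(x)
}
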