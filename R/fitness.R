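#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall and F-measure from raw confusion
#' counts. Degenerate zero-denominator cases (e.g. no predicted positives)
#' return 0 for the affected metric with a warning, a common convention that
#' keeps multi-run averaging well defined.
#'
#' @param tp,tn,fp,fn Non-negative integer counts; at least one sample.
#' @return A named list: `accuracy`, `precision`, `recall`, `f_measure`.
#' @examples
#' confusion_metrics(tp = 8, tn = 7, fp = 2, fn = 3)
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  total <- tp + tn + fp + fn
  if (total == 0) stop("no scored samples (all counts zero)", call. = FALSE)
  ratio0 <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); returning 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- ratio0(tp, tp + fp, "precision")
  recall    <- ratio0(tp, tp + fn, "recall")
  f_measure <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(
    accuracy  = (tp + tn) / total,
    precision = precision,
    recall    = recall,
    f_measure = f_measure
  )
}

#' Biobjective feature-selection fitness
#'
#' Scalarizes the two wrapper objectives -- maximize cross-validated
#' accuracy, minimize subset size -- as
#' \eqn{fit = (1 - \alpha) S / D - \alpha \cdot AvgAcc},
#' to be minimized. The weight \eqn{\alpha} (default 0.8) puts most of the
#' emphasis on accuracy; the remaining \eqn{1 - \alpha} charges each
#' selected feature a cost of \eqn{(1-\alpha)/D}. The equivalent error-form
#' \eqn{(1-\alpha) S/D + \alpha (1 - AvgAcc)} differs only by the constant
#' \eqn{\alpha} and induces the same ranking of masks.
#'
#' @param avg_acc Mean cross-validated accuracy in `[0, 1]`.
#' @param s Number of selected features, `1 <= s <= d`.
#' @param d Total number of features.
#' @param alpha Accuracy weight in `(0, 1)`, default 0.8.
#' @return The fitness value (lower is better).
#' @export
fitness_from_accuracy <- function(avg_acc, s, d, alpha = 0.8) {
  if (any(s == 0)) stop("empty feature subset: fitness undefined", call. = FALSE)
  if (any(s < 0) || any(s > d)) stop("`s` must satisfy 1 <= s <= d", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (any(avg_acc < 0) || any(avg_acc > 1)) {
    stop("`avg_acc` must be in [0, 1]", call. = FALSE)
  }
  (1 - alpha) * (s / d) - alpha * avg_acc
}

## Stratified fold assignment: class proportions preserved per fold.
## Tiny classes (high-dimensional biomedical sets have 20-40 per class)
## make plain random folds prone to single-class training partitions.
stratified_folds <- function(y, folds) {
  if (folds < 2L) stop("`folds` must be >= 2", call. = FALSE)
  fold_id <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < folds) {
      stop(sprintf(
        "class %s has %d samples, fewer than %d folds: stratification impossible",
        cls, length(idx), folds), call. = FALSE)
    }
    fold_id[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

## Deterministic KNN prediction for one test block.
## Neighbour distance ties -> lowest training index (order() is stable);
## vote ties (even k) -> class 1.
knn_predict_block <- function(d2_test_train, y_train, k) {
  apply(d2_test_train, 1L, function(dr) {
    nb <- y_train[order(dr)[seq_len(k)]]
    n1 <- sum(nb == 1L)
    as.integer(n1 >= k - n1)
  })
}

#' KNN cross-validated accuracy of a feature mask
#'
#' Restricts the feature matrix to the masked columns and scores it by
#' stratified k-fold cross-validation of a k-nearest-neighbour classifier
#' with Euclidean distance and majority vote. Returns the mean of the
#' per-fold accuracies together with the confusion counts pooled over all
#' folds (every sample is scored exactly once as a held-out point).
#'
#' Tie handling is deterministic so runs replay exactly: equidistant
#' neighbours are resolved toward the lowest sample index and tied votes
#' toward class 1.
#'
#' @param x Numeric matrix, samples in rows (normalized features).
#' @param y Integer 0/1 label vector.
#' @param mask Integer 0/1 vector over columns of `x`; must select at least
#'   one feature.
#' @param k Neighbour count (default 5).
#' @param folds Fold count (default 10).
#' @param fold_id Optional precomputed fold assignment (integer vector in
#'   `1:folds`); if `NULL`, a stratified assignment is drawn from the global
#'   random stream.
#' @return A list: `avg_acc` (mean per-fold accuracy), `pooled` (named
#'   vector `tp`, `tn`, `fp`, `fn`), `fold_acc` (per-fold accuracies).
#' @export
knn_cv_accuracy <- function(x, y, mask = rep(1L, ncol(x)), k = 5L,
                            folds = 10L, fold_id = NULL) {
  if (length(mask) != ncol(x)) {
    stop("`mask` length must equal ncol(x)", call. = FALSE)
  }
  sel <- which(mask == 1L)
  if (length(sel) == 0L) stop("empty feature subset", call. = FALSE)
  if (length(unique(y)) != 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  if (is.null(fold_id)) fold_id <- stratified_folds(y, folds)

  # one pairwise squared-distance matrix per mask; folds reuse it
  d2 <- as.matrix(stats::dist(x[, sel, drop = FALSE]))^2
  pooled <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    test  <- which(fold_id == f)
    train <- which(fold_id != f)
    if (length(train) < k) {
      stop("training partition smaller than k", call. = FALSE)
    }
    pred <- knn_predict_block(d2[test, train, drop = FALSE], y[train], k)
    truth <- y[test]
    pooled <- pooled + c(
      tp = sum(pred == 1L & truth == 1L),
      tn = sum(pred == 0L & truth == 0L),
      fp = sum(pred == 1L & truth == 0L),
      fn = sum(pred == 0L & truth == 1L)
    )
    fold_acc[f] <- mean(pred == truth)
  }
  list(avg_acc = mean(fold_acc), pooled = pooled, fold_acc = fold_acc)
}

#' Build a memoized KNN fitness evaluator
#'
#' Returns the fitness callback consumed by [run_gwo()]: a function taking
#' an integer 0/1 mask and returning a report with `fitness`, `avg_acc`,
#' `n_selected`, `n_features` and pooled confusion counts. The stratified
#' fold assignment is drawn once at construction (from `cv_seed` if given),
#' so every mask is scored against the same partition and results are
#' comparable across the whole run. Reports are memoized by mask bits:
#' re-evaluating an unchanged wolf is free.
#'
#' An empty mask yields a sentinel worst report (`fitness = 1`, larger than
#' any reachable value, which lies in \eqn{[-\alpha, 1 - \alpha]}), keeping
#' the optimizer loop alive when binarization zeroes a wolf.
#'
#' @param x Numeric matrix of normalized features, samples in rows.
#' @param y Integer 0/1 labels.
#' @param k KNN neighbour count (default 5).
#' @param folds CV fold count (default 10).
#' @param alpha Fitness accuracy weight (default 0.8).
#' @param cv_seed Optional seed for the fold assignment; drawn from the
#'   global stream when `NULL`.
#' @return A function `(mask) -> report`; its environment carries the cache
#'   and the fold assignment (attribute `fold_id`).
#' @export
make_knn_evaluator <- function(x, y, k = 5L, folds = 10L, alpha = 0.8,
                               cv_seed = NULL) {
  if (!is.null(cv_seed)) {
    fold_id <- local({ set.seed(cv_seed); stratified_folds(y, folds) })
  } else {
    fold_id <- stratified_folds(y, folds)
  }
  d_total <- ncol(x)
  cache <- new.env(parent = emptyenv())
  sentinel <- list(fitness = 1, avg_acc = NA_real_, n_selected = 0L,
                   n_features = d_total,
                   pooled = c(tp = NA, tn = NA, fp = NA, fn = NA))
  ev <- function(mask) {
    s <- sum(mask)
    if (s == 0L) return(sentinel)
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cv <- knn_cv_accuracy(x, y, mask, k = k, folds = folds, fold_id = fold_id)
    rep <- list(
      fitness = fitness_from_accuracy(cv$avg_acc, s, d_total, alpha),
      avg_acc = cv$avg_acc,
      n_selected = as.integer(s),
      n_features = d_total,
      pooled = cv$pooled
    )
    cache[[key]] <- rep
    rep
  }
  attr(ev, "fold_id") <- fold_id
  ev
}

#' Score a feature mask on a dataset
#'
#' Convenience one-shot evaluation of a mask: KNN cross-validated accuracy,
#' the biobjective fitness, and the pooled confusion metrics. This is the
#' final-report path used after optimization; it does not share the
#' optimizer's memoization cache.
#'
#' @param x Numeric matrix of normalized features.
#' @param y Integer 0/1 labels.
#' @param mask Integer 0/1 vector over columns.
#' @param k,folds,alpha As in [make_knn_evaluator()].
#' @param cv_seed Seed for the stratified fold assignment.
#' @return A list: `fitness`, `avg_acc`, `n_selected`, `metrics` (from
#'   [confusion_metrics()] on the pooled counts), `pooled`.
#' @export
evaluate_mask <- function(x, y, mask, k = 5L, folds = 10L, alpha = 0.8,
                          cv_seed = NULL) {
  if (!is.null(cv_seed)) set.seed(cv_seed)
  fold_id <- stratified_folds(y, folds)
  cv <- knn_cv_accuracy(x, y, mask, k = k, folds = folds, fold_id = fold_id)
  p <- as.list(cv$pooled)
  list(
    fitness = fitness_from_accuracy(cv$avg_acc, sum(mask), ncol(x), alpha),
    avg_acc = cv$avg_acc,
    n_selected = as.integer(sum(mask)),
    metrics = confusion_metrics(p$tp, p$tn, p$fp, p$fn),
    pooled = cv$pooled
  )
}
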