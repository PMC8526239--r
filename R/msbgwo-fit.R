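#' Fit a grey-wolf wrapper feature selector
#'
#' Runs the master-slave binary grey wolf optimizer (MSBGWO, the default) or
#' the plain binary grey wolf optimizer (BGWO2) to select a feature subset
#' for a two-class problem. Candidate subsets are binary wolf positions,
#' moved by leader-guided grey-wolf updates (and, for MSBGWO, an additional
#' master-slave learning step each iteration in which the weaker half of the
#' pack takes a randomized step toward the fitter half). Each subset is
#' scored by the stratified k-fold cross-validated accuracy of a KNN
#' classifier, combined with a subset-size penalty:
#' \eqn{fit = (1 - \alpha) S / D - \alpha \cdot AvgAcc} (minimized).
#'
#' After the search, the best mask found is re-scored with a fresh
#' cross-validation split to produce the reported metrics, so reported
#' numbers are decoupled from the optimizer's internal cache.
#'
#' @param x Feature matrix (samples in rows), a formula, or an
#'   `"msbgwo_dataset"`.
#' @param ... Passed on to methods.
#' @return An object of class `"msbgwo"`; see [summary.msbgwo()].
#' @seealso [generate_synthetic()], [run_experiment()]
#' @examples
#' syn <- generate_synthetic(n = 40, n_features = 20, n_informative = 3,
#'                           seed = 1)
#' fit <- msbgwo(syn$dataset, iterations = 10, seed = 1)
#' summary(fit)
#' @export
msbgwo <- function(x, ...) UseMethod("msbgwo")

#' @rdname msbgwo
#' @param y Binary labels: integer 0/1, or a 2-level factor/character vector
#'   (the second sorted level is treated as positive).
#' @param variant `"msbgwo"` (master-slave, nonlinear schedule) or
#'   `"bgwo2"` (plain leader updates, linear schedule).
#' @param pop_size Population size N, even, default 10.
#' @param iterations Iteration budget T, default 100.
#' @param omega Master-slave learning coefficient in `[0, 1]`, default 0.1;
#'   ignored by BGWO2.
#' @param alpha Fitness accuracy weight, default 0.8.
#' @param k KNN neighbour count, default 5.
#' @param folds Cross-validation folds, default 10.
#' @param normalize Min-max normalize features first (default TRUE; skipped
#'   when the input dataset is already normalized).
#' @param seed Optional integer seed; a seeded fit is exactly replayable.
#' @export
msbgwo.default <- function(x, y, variant = c("msbgwo", "bgwo2"),
                           pop_size = 10L, iterations = 100L, omega = 0.1,
                           alpha = 0.8, k = 5L, folds = 10L,
                           normalize = TRUE, seed = NULL, ...) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  if (is.character(y)) y <- factor(y)
  lab <- c("0", "1")
  if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("`y` must have exactly 2 levels", call. = FALSE)
    lab <- levels(y)
    y <- as.integer(y) - 1L
  }
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("`y` must be binary 0/1", call. = FALSE)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  ds <- new_dataset(x, y, positive_label = lab[2L], negative_label = lab[1L])
  prep <- NULL
  if (normalize) {
    ds <- minmax_normalize(ds)
    prep <- list(min = ds$norm_min, span = ds$norm_span)
  }
  fit_gwo_dataset(ds, variant, pop_size, iterations, omega, alpha, k,
                  folds, seed, cl = match.call(), prep = prep)
}

#' @rdname msbgwo
#' @export
msbgwo.msbgwo_dataset <- function(x, variant = c("msbgwo", "bgwo2"),
                                  pop_size = 10L, iterations = 100L,
                                  omega = 0.1, alpha = 0.8, k = 5L,
                                  folds = 10L, seed = NULL, ...) {
  variant <- match.arg(variant)
  prep <- NULL
  if (x$normalized) {
    ds <- x   # new samples are expected on the same (normalized) scale
  } else {
    ds <- minmax_normalize(x)
    prep <- list(min = ds$norm_min, span = ds$norm_span)
  }
  fit_gwo_dataset(ds, variant, pop_size, iterations, omega, alpha, k,
                  folds, seed, cl = match.call(), prep = prep)
}

#' @rdname msbgwo
#' @param formula A formula such as `class ~ .` naming the label column.
#' @param data A data frame holding the label and feature columns.
#' @export
msbgwo.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  feats <- mf[, -1L, drop = FALSE]
  msbgwo.default(as.matrix(feats), y, ...)
}

fit_gwo_dataset <- function(ds, variant, pop_size, iterations, omega, alpha,
                            k, folds, seed, cl, prep = NULL) {
  # one seeded stream per fit: fold assignment, init, updates, final CV
  # all consume it in this fixed order
  if (!is.null(seed)) set.seed(seed)
  evaluate <- make_knn_evaluator(ds$x, ds$y, k = k, folds = folds,
                                 alpha = alpha)
  trace <- run_gwo(evaluate, ncol(ds$x), variant = variant,
                   pop_size = pop_size, iterations = iterations,
                   omega = omega, seed = NULL)
  final <- evaluate_mask(ds$x, ds$y, trace$best_mask, k = k, folds = folds,
                         alpha = alpha)
  structure(list(
    call = cl,
    variant = variant,
    mask = stats::setNames(trace$best_mask, ds$feature_names),
    selected = ds$feature_names[trace$best_mask == 1L],
    fitness = trace$best_fitness,
    convergence = trace$convergence,
    cv = final,
    config = list(pop_size = pop_size, iterations = iterations,
                  omega = omega, alpha = alpha, k = k, folds = folds,
                  seed = seed),
    n_evaluations = trace$n_evaluations,
    dataset = ds,
    prep = prep
  ), class = "msbgwo")
}

#' @export
print.msbgwo <- function(x, ...) {
  cat(sprintf("%s wrapper feature selection\n", toupper(x$variant)))
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("Selected %d of %d features; CV accuracy %.3f; fitness %.4f\n",
              length(x$selected), length(x$mask), x$cv$avg_acc, x$fitness))
  invisible(x)
}

#' Summarize a fitted grey-wolf feature selector
#'
#' @param object A fitted `"msbgwo"` object.
#' @param ... Unused.
#' @return A list of class `"summary.msbgwo"` with the selection, the final
#'   cross-validated metric set (accuracy, precision, recall, F-measure on
#'   pooled confusion counts) and the run configuration.
#' @export
summary.msbgwo <- function(object, ...) {
  structure(list(
    call = object$call,
    variant = object$variant,
    n_selected = length(object$selected),
    n_features = length(object$mask),
    selected = object$selected,
    fitness = object$fitness,
    avg_acc = object$cv$avg_acc,
    metrics = object$cv$metrics,
    config = object$config,
    n_evaluations = object$n_evaluations
  ), class = "summary.msbgwo")
}

#' @export
print.summary.msbgwo <- function(x, ...) {
  cat(sprintf("%s wrapper feature selection\n", toupper(x$variant)))
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  cat(sprintf("Features selected: %d / %d\n", x$n_selected, x$n_features))
  cat(sprintf("Fitness (lower is better): %.4f\n", x$fitness))
  cat(sprintf("10x-CV accuracy (AvgAcc):  %.4f\n", x$avg_acc))
  m <- x$metrics
  cat(sprintf("Pooled precision %.4f, recall %.4f, F-measure %.4f\n",
              m$precision, m$recall, m$f_measure))
  cat(sprintf("Fitness evaluations: %d (N=%d, T=%d)\n",
              x$n_evaluations, x$config$pop_size, x$config$iterations))
  if (x$n_selected <= 25L) {
    cat("Selected: ", paste(x$selected, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract the selected-feature mask
#'
#' @param object A fitted `"msbgwo"` object.
#' @param ... Unused.
#' @return Named integer 0/1 vector over all features (1 = selected).
#' @export
coef.msbgwo <- function(object, ...) object$mask

cross_dist2 <- function(a, b) {
  # squared Euclidean cross-distances, rows of a vs rows of b
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Predict class labels with the selected features
#'
#' Classifies new samples by the same KNN rule the wrapper optimized:
#' majority vote among the `k` Euclidean-nearest training samples,
#' restricted to the selected features, with the deterministic tie rules
#' used throughout (distance ties to the lowest training index, vote ties
#' to the positive class). When normalization was fitted inside [msbgwo()],
#' new data is mapped through the training min-max ranges first; when an
#' already-normalized dataset was supplied, new samples are expected on that
#' same scale.
#'
#' @param object A fitted `"msbgwo"` object.
#' @param newdata Matrix or data frame with the training feature columns.
#' @param type `"label"` for original class labels, `"numeric"` for 0/1.
#' @param ... Unused.
#' @return Vector of predicted labels.
#' @export
predict.msbgwo <- function(object, newdata, type = c("label", "numeric"),
                           ...) {
  type <- match.arg(type)
  ds <- object$dataset
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(ds$x)) {
    stop("`newdata` must have the training feature columns", call. = FALSE)
  }
  if (!is.null(object$prep)) {  # normalization was fitted inside msbgwo()
    newdata <- sweep(sweep(newdata, 2L, object$prep$min, "-"),
                     2L, object$prep$span, "/")
  }
  sel <- which(object$mask == 1L)
  d2 <- cross_dist2(newdata[, sel, drop = FALSE],
                    ds$x[, sel, drop = FALSE])
  pred <- knn_predict_block(d2, ds$y, object$config$k)
  if (type == "numeric") return(pred)
  ifelse(pred == 1L, ds$positive_label, ds$negative_label)
}

#' Plot the convergence of a fitted selector
#'
#' Draws the per-iteration best-so-far fitness, which is non-increasing by
#' construction (leaders are retained until beaten).
#'
#' @param x A fitted `"msbgwo"` object.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.msbgwo <- function(x, ...) {
  graphics::plot(seq_along(x$convergence), x$convergence, type = "s",
                 xlab = "iteration", ylab = "best-so-far fitness",
                 main = sprintf("%s convergence", toupper(x$variant)), ...)
  invisible(x)
}
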