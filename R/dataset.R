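#' Load a two-class dataset from delimited text
#'
#' Reads a CSV (or TSV, auto-detected from the header line) with one header
#' row, numeric feature columns and one label column holding exactly two
#' distinct labels. The label mapped to 1 is `positive_label` if given,
#' otherwise the lexicographically larger label; precision and recall treat
#' class 1 as positive.
#'
#' @param path Path to the delimited text file.
#' @param label_column Name of the label column (default `"class"`).
#' @param positive_label Optional label value to encode as 1.
#' @return An object of class `"msbgwo_dataset"`: a list with `x` (numeric
#'   matrix, samples in rows), `y` (integer 0/1), `feature_names`,
#'   `positive_label`, and `normalized = FALSE`.
#' @export
load_dataset <- function(path, label_column = "class", positive_label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!label_column %in% names(df)) {
    stop(sprintf("label column '%s' not found (columns: %s)",
                 label_column, paste(names(df), collapse = ", ")),
         call. = FALSE)
  }
  labels <- as.character(df[[label_column]])
  feat <- df[setdiff(names(df), label_column)]
  if (anyDuplicated(names(feat))) {
    stop("duplicate feature names: ",
         paste(unique(names(feat)[duplicated(names(feat))]), collapse = ", "),
         call. = FALSE)
  }
  for (j in seq_along(feat)) {
    if (!is.numeric(feat[[j]])) {
      stop(sprintf("non-numeric values in feature column '%s'",
                   names(feat)[j]), call. = FALSE)
    }
  }
  if (anyNA(feat) || anyNA(labels)) {
    bad <- which(rowSums(is.na(feat)) > 0 | is.na(labels))
    stop("missing values in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    stop(sprintf("expected exactly 2 classes, found %d: %s",
                 length(lv), paste(lv, collapse = ", ")), call. = FALSE)
  }
  if (is.null(positive_label)) positive_label <- lv[2L]
  if (!positive_label %in% lv) {
    stop(sprintf("positive_label '%s' not among labels (%s)",
                 positive_label, paste(lv, collapse = ", ")), call. = FALSE)
  }
  new_dataset(as.matrix(feat), as.integer(labels == positive_label),
              positive_label = positive_label,
              negative_label = lv[lv != positive_label])
}

new_dataset <- function(x, y, positive_label = "1", negative_label = "0",
                        normalized = FALSE) {
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) {
    colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  }
  structure(list(
    x = x, y = as.integer(y),
    feature_names = colnames(x),
    positive_label = positive_label,
    negative_label = negative_label,
    normalized = normalized
  ), class = "msbgwo_dataset")
}

#' @export
print.msbgwo_dataset <- function(x, ...) {
  cat(sprintf("Two-class dataset: %d samples x %d features (%s)\n",
              nrow(x$x), ncol(x$x),
              if (x$normalized) "normalized" else "raw"))
  cat(sprintf("  class 1 ('%s'): %d, class 0: %d\n",
              x$positive_label, sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' Write a dataset to CSV
#'
#' Serializes features plus a `class` label column; [load_dataset()] on the
#' result reproduces `x` and `y` exactly.
#'
#' @param ds An `"msbgwo_dataset"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "msbgwo_dataset"))
  df <- as.data.frame(ds$x)
  df$class <- ifelse(ds$y == 1L, ds$positive_label, ds$negative_label)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Min-max normalize every feature column
#'
#' Maps each column to \eqn{(x - \min) / (\max - \min)} so all features lie
#' in `[0, 1]` -- the preprocessing a Euclidean KNN needs so no single
#' high-scale feature dominates the distance. Constant columns (zero range)
#' map to all-zeros with a warning. Idempotent: normalizing a normalized
#' dataset returns it unchanged.
#'
#' Normalization is global, fitted on the full dataset before any
#' cross-validation split; see the methods vignette for the rationale and
#' the (mild) optimism this implies.
#'
#' @param ds An `"msbgwo_dataset"`.
#' @return The dataset with normalized `x` and `normalized = TRUE`.
#' @export
minmax_normalize <- function(ds) {
  stopifnot(inherits(ds, "msbgwo_dataset"))
  if (ds$normalized) return(ds)
  rng <- apply(ds$x, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  const <- span == 0
  if (any(const)) {
    warning(sprintf("%d constant column(s) mapped to all-zeros", sum(const)),
            call. = FALSE)
    span[const] <- 1
  }
  x <- sweep(sweep(ds$x, 2L, rng[1L, ], "-"), 2L, span, "/")
  x[, const] <- 0
  ds$x <- x
  ds$normalized <- TRUE
  ds$norm_min <- rng[1L, ]   # kept so new samples can be mapped identically
  ds$norm_span <- span
  ds
}

#' Generate a synthetic high-dimensional two-class dataset
#'
#' Emulates the shape of gene-expression-style classification problems:
#' many more features than samples, two classes, and a small set of
#' class-informative features hidden among pure noise. Noise features are
#' standard normal for all samples; each planted feature has
#' class-conditional means 0 (class 0) and `effect` (class 1) with unit
#' variance, so `effect` is the class separation in within-class standard
#' deviations. Columns are min-max normalized afterwards. The planted
#' column indices are returned as ground truth for selection-quality tests.
#'
#' Defaults mirror a colon-cancer-scale problem (62 samples, 2000 features,
#' 10 informative, a strong 2-SD shift, balanced classes).
#'
#' @param n Number of samples (default 62).
#' @param n_features Total feature count D (default 2000).
#' @param n_informative Number of planted informative features (default 10).
#' @param effect Class-mean shift of planted features, in within-class SD
#'   units (default 2).
#' @param class_balance Fraction of samples in class 1 (default 0.5).
#' @param seed Optional integer seed.
#' @return A list: `dataset` (an `"msbgwo_dataset"`, normalized) and
#'   `planted` (integer indices of the informative columns).
#' @examples
#' syn <- generate_synthetic(n = 40, n_features = 30, n_informative = 3,
#'                           seed = 1)
#' syn$planted
#' @export
generate_synthetic <- function(n = 62L, n_features = 2000L,
                               n_informative = 10L, effect = 2,
                               class_balance = 0.5, seed = NULL) {
  if (n_informative < 1L || n_informative > n_features) {
    stop("`n_informative` must be in [1, n_features]", call. = FALSE)
  }
  if (class_balance <= 0 || class_balance >= 1) {
    stop("`class_balance` must be in (0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n1 <- round(n * class_balance)
  if (n1 < 1L || n1 > n - 1L) {
    stop("class balance leaves a class empty", call. = FALSE)
  }
  y <- sample(rep(c(1L, 0L), c(n1, n - n1)))
  x <- matrix(stats::rnorm(n * n_features), nrow = n)
  planted <- sort(sample.int(n_features, n_informative))
  x[, planted] <- x[, planted] + effect * y  # shift class 1 on planted cols
  colnames(x) <- sprintf("f%04d", seq_len(n_features))
  ds <- minmax_normalize(new_dataset(x, y, positive_label = "1"))
  list(dataset = ds, planted = planted)
}

#' Write a synthetic dataset with its ground-truth sidecar
#'
#' Writes the dataset as CSV plus a JSON sidecar (`<path>.json`) recording
#' the planted indices and generator settings, so downstream evaluation can
#' recover the ground truth.
#'
#' @param syn A list as returned by [generate_synthetic()].
#' @param path CSV output path.
#' @param spec Optional named list of generator settings to record.
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(syn, path, spec = NULL) {
  write_dataset(syn$dataset, path)
  sidecar <- list(planted = syn$planted, spec = spec)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
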