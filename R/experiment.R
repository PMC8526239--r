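#' Average per-run metrics across repeated optimizer runs
#'
#' Stochastic optimizers are summarized over k independent runs by the
#' arithmetic means of accuracy, precision, recall, F-measure and
#' selected-feature count, plus the max, min and sample standard deviation
#' of accuracy.
#'
#' @param runs Data frame of per-run records with columns `accuracy`,
#'   `precision`, `recall`, `f_measure`, `n_selected`.
#' @return A one-row data frame: `max_acc`, `min_acc`, `avg_acc`, `sd_acc`,
#'   `avg_sf`, `avg_pre`, `avg_rec`, `avg_f`, `k`.
#' @export
average_runs <- function(runs) {
  if (nrow(runs) == 0L) stop("no runs to average", call. = FALSE)
  data.frame(
    max_acc = max(runs$accuracy),
    min_acc = min(runs$accuracy),
    avg_acc = mean(runs$accuracy),
    sd_acc  = if (nrow(runs) > 1L) stats::sd(runs$accuracy) else 0,
    avg_sf  = mean(runs$n_selected),
    avg_pre = mean(runs$precision),
    avg_rec = mean(runs$recall),
    avg_f   = mean(runs$f_measure),
    k       = nrow(runs)
  )
}

#' Wilcoxon rank-sum comparison of two optimizers
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of equal medians between
#' two sets of per-run scores, using the midrank normal approximation with
#' tie correction and no continuity correction, which exposes the z
#' statistic alongside the p value. `h = 1` rejects equality at the given
#' significance level. If every value in both samples is identical the
#' variance degenerates; the test then returns `p = 1`, `h = 0`, `z = 0`.
#'
#' @param a,b Numeric vectors of per-run scores (e.g. accuracies).
#' @param level Significance level, default 0.05.
#' @return A list: `p_value`, `h` (0/1), `z`, `w` (rank sum of `a`).
#' @export
wilcoxon_compare <- function(a, b, level = 0.05) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))  # midranks for ties
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(p_value = 1, h = 0L, z = 0, w = w))
  }
  z <- (w - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  list(p_value = p, h = as.integer(p < level), z = z, w = w)
}

## Per-run seed: pure function of (base seed, variant, run index), so adding
## a variant or run never perturbs another's random stream. Kept < 2^31.
run_seed <- function(base_seed, variant, run) {
  code <- sum(utf8ToInt(variant))
  ((base_seed %% 100000L) * 10007 + code * 1009 + run) %% 2147483647
}

#' Run the full multi-run comparison protocol
#'
#' Executes `runs` independently seeded fits per optimizer variant on one
#' dataset, re-evaluates each run's best mask with a fresh stratified
#' cross-validation to obtain its reported metrics, averages the runs per
#' variant, and tests every variant pair with the Wilcoxon rank-sum test on
#' per-run accuracies. Per-run seeds are a pure function of the base seed,
#' the variant name and the run index, so the whole experiment is exactly
#' reproducible and variants can be added without perturbing each other.
#'
#' When `out_dir` is given, three files are written: `runs.csv` (one row
#' per run, with the convergence series semicolon-joined), `summary.json`
#' (per-variant averages plus the Wilcoxon block) and `summary.txt` (a
#' human-readable table).
#'
#' @param dataset An `"msbgwo_dataset"` (normalized automatically), or a
#'   path to a CSV/TSV accepted by [load_dataset()].
#' @param variants Character vector of optimizers to run (default both
#'   `"msbgwo"` and `"bgwo2"`).
#' @param runs Number of repeated runs per variant, default 10.
#' @param base_seed Base seed for the per-run seed derivation, default 1.
#' @param pop_size,iterations,omega,alpha,k,folds Optimizer and fitness
#'   settings, as in [msbgwo()].
#' @param out_dir Optional output directory for report files.
#' @param label_column,positive_label Passed to [load_dataset()] when
#'   `dataset` is a path.
#' @return A list of class `"msbgwo_experiment"`: `runs` (per-run data
#'   frame), `summary` (per-variant data frame), `wilcoxon` (data frame of
#'   pairwise comparisons), `config`.
#' @examples
#' \donttest{
#' syn <- generate_synthetic(n = 40, n_features = 20, n_informative = 3,
#'                           seed = 1)
#' ex <- run_experiment(syn$dataset, runs = 2, iterations = 5)
#' ex$summary
#' }
#' @export
run_experiment <- function(dataset, variants = c("msbgwo", "bgwo2"),
                           runs = 10L, base_seed = 1L,
                           pop_size = 10L, iterations = 100L, omega = 0.1,
                           alpha = 0.8, k = 5L, folds = 10L,
                           out_dir = NULL, label_column = "class",
                           positive_label = NULL) {
  if (runs < 1L) stop("`runs` must be >= 1", call. = FALSE)
  if (is.character(dataset)) {
    dataset <- load_dataset(dataset, label_column, positive_label)
  }
  stopifnot(inherits(dataset, "msbgwo_dataset"))
  ds <- if (dataset$normalized) dataset else minmax_normalize(dataset)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  rows <- list()
  for (v in variants) {
    for (i in seq_len(runs)) {
      sd_i <- run_seed(base_seed, v, i)
      fit <- msbgwo(ds, variant = v, pop_size = pop_size,
                    iterations = iterations, omega = omega, alpha = alpha,
                    k = k, folds = folds, seed = sd_i)
      m <- fit$cv$metrics
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, run = i, seed = sd_i,
        accuracy = fit$cv$avg_acc, precision = m$precision,
        recall = m$recall, f_measure = m$f_measure,
        n_selected = length(fit$selected), fitness = fit$fitness,
        selected = paste(fit$selected, collapse = ";"),
        convergence = paste(signif(fit$convergence, 8), collapse = ";")
      )
    }
  }
  run_df <- do.call(rbind, rows)

  summ <- do.call(rbind, lapply(variants, function(v) {
    cbind(variant = v, average_runs(run_df[run_df$variant == v, ]))
  }))

  wil <- NULL
  if (length(variants) >= 2L) {
    prs <- utils::combn(variants, 2L)
    wil <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      va <- prs[1L, j]; vb <- prs[2L, j]
      wc <- wilcoxon_compare(run_df$accuracy[run_df$variant == va],
                             run_df$accuracy[run_df$variant == vb])
      data.frame(comparison = paste(va, "vs", vb),
                 p_value = wc$p_value, h = wc$h, z = wc$z)
    }))
  }

  res <- structure(list(runs = run_df, summary = summ, wilcoxon = wil,
                        config = list(variants = variants, runs = runs,
                                      base_seed = base_seed,
                                      pop_size = pop_size,
                                      iterations = iterations,
                                      omega = omega, alpha = alpha,
                                      k = k, folds = folds)),
                   class = "msbgwo_experiment")
  if (!is.null(out_dir)) write_experiment(res, out_dir)
  res
}

write_experiment <- function(res, out_dir) {
  utils::write.csv(res$runs, file.path(out_dir, "runs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = res$summary, wilcoxon = res$wilcoxon,
         config = res$config),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  txt <- utils::capture.output(print(res))
  writeLines(txt, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}

#' @export
print.msbgwo_experiment <- function(x, ...) {
  cat(sprintf("Optimizer comparison: %d run(s) per variant (N=%d, T=%d)\n\n",
              x$config$runs, x$config$pop_size, x$config$iterations))
  s <- x$summary
  tab <- data.frame(
    Algorithm = toupper(s$variant),
    Max = sprintf("%.3f", s$max_acc),
    Min = sprintf("%.3f", s$min_acc),
    AvgAcc = sprintf("%.3f ± %.3f", s$avg_acc, s$sd_acc),
    AvgSF = sprintf("%.1f", s$avg_sf),
    AvgPre = sprintf("%.3f", s$avg_pre),
    AvgRec = sprintf("%.3f", s$avg_rec),
    AvgF = sprintf("%.3f", s$avg_f)
  )
  print(tab, row.names = FALSE)
  if (!is.null(x$wilcoxon)) {
    cat("\nWilcoxon rank sum test (5% level) on per-run accuracies:\n")
    w <- x$wilcoxon
    wt <- data.frame(Comparison = w$comparison,
                     p.value = sprintf("%.4e", w$p_value),
                     h = w$h, z = sprintf("%.4f", w$z))
    print(wt, row.names = FALSE)
  }
  invisible(x)
}

#' Box plots of per-run metrics by optimizer
#'
#' Draws side-by-side box plots of the per-run accuracy, precision, recall
#' and F-measure for each optimizer variant in an experiment.
#'
#' @param x An `"msbgwo_experiment"`.
#' @param ... Further arguments to [graphics::boxplot()].
#' @export
plot.msbgwo_experiment <- function(x, ...) {
  op <- graphics::par(mfrow = c(2L, 2L))
  on.exit(graphics::par(op))
  for (m in c("accuracy", "precision", "recall", "f_measure")) {
    graphics::boxplot(stats::as.formula(paste(m, "~ variant")),
                      data = x$runs, main = m, xlab = "", ylab = m, ...)
  }
  invisible(x)
}
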