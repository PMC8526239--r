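# Fixture builders shared across test files. Everything is generated in
# code so tests carry no stored data.

# Two perfectly separated point clouds: class 0 near feature value 0,
# class 1 near 1, on every feature. KNN should be perfect on any subset.
make_separable <- function(n_per_class = 20L, d = 4L, seed = 42L) {
  set.seed(seed)
  x <- rbind(
    matrix(stats::rnorm(n_per_class * d, 0, 0.02), ncol = d),
    matrix(stats::rnorm(n_per_class * d, 1, 0.02), ncol = d)
  )
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = rep(c(0L, 1L), each = n_per_class))
}

# Pure-noise dataset: labels independent of features.
make_noise <- function(n = 60L, d = 20L, seed = 7L) {
  set.seed(seed)
  x <- matrix(stats::runif(n * d), ncol = d)
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = rep(c(0L, 1L), length.out = n))
}

# Independent scalar-loop oracle for the leader-guided move, driven by
# pre-recorded coefficient draws (A1..A3, C1..C3 per dimension).
oracle_leader_move <- function(x, al, be, de, A, C) {
  d <- length(x)
  out <- numeric(d)
  for (j in seq_len(d)) {
    x1 <- al[j] - A[[1]][j] * abs(C[[1]][j] * al[j] - x[j])
    x2 <- be[j] - A[[2]][j] * abs(C[[2]][j] * be[j] - x[j])
    x3 <- de[j] - A[[3]][j] * abs(C[[3]][j] * de[j] - x[j])
    out[j] <- (x1 + x2 + x3) / 3
  }
  out
}

# Brute-force confusion counter over prediction/label vectors.
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (pred[i] == 1L && truth[i] == 1L) tp <- tp + 1L
    else if (pred[i] == 0L && truth[i] == 0L) tn <- tn + 1L
    else if (pred[i] == 1L && truth[i] == 0L) fp <- fp + 1L
    else fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Exhaustive two-sided permutation p-value for the rank-sum statistic:
# enumerates every assignment of the pooled midranks to group A.
oracle_ranksum_perm <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (length(r) + 1) / 2
  combos <- utils::combn(length(r), n1)
  ws <- apply(combos, 2L, function(idx) sum(r[idx]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
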