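#' Encircling-coefficient schedule
#'
#' The control parameter \eqn{a} governs the exploration/exploitation balance
#' of the grey wolf search: step coefficients are drawn from \eqn{[-a, a]},
#' so large \eqn{a} permits moves that overshoot the leaders (exploration)
#' and \eqn{a \to 0} contracts the pack onto them (exploitation). Two decay
#' schedules from 2 to 0 are supported: the classic linear
#' \eqn{a = 2 - 2t/T} (used by BGWO2) and the quadratic nonlinear
#' \eqn{a = 2(1 - t^2/T^2)} (used by MSBGWO), which stays high for longer and
#' therefore lengthens the exploratory phase.
#'
#' @param t Iteration index, `0 <= t <= T` (vectorized).
#' @param T_max Maximum number of iterations, `>= 1`.
#' @param schedule `"linear"` or `"nonlinear"`.
#' @return The value(s) of `a`, in `[0, 2]`, non-increasing in `t`.
#' @examples
#' control_param(50, 100, "linear")     # 1.0
#' control_param(50, 100, "nonlinear")  # 1.5
#' @export
control_param <- function(t, T_max, schedule = c("linear", "nonlinear")) {
  schedule <- match.arg(schedule)
  if (!is.numeric(T_max) || length(T_max) != 1L || T_max < 1) {
    stop("`T_max` must be a single number >= 1", call. = FALSE)
  }
  if (any(t < 0) || any(t > T_max)) {
    stop("`t` must satisfy 0 <= t <= T_max", call. = FALSE)
  }
  switch(schedule,
    linear    = 2 - 2 * t / T_max,
    nonlinear = 2 * (1 - t^2 / T_max^2)
  )
}

#' Draw one pair of grey-wolf step coefficients
#'
#' Draws the per-dimension coefficient vectors \eqn{A = 2a r_1 - a} and
#' \eqn{C = 2 r_2}, with \eqn{r_1, r_2} fresh uniform(0,1) vectors. `A`
#' scales the step toward (or past) a leader; `C` randomly re-weights the
#' leader's position in the distance term. Each call consumes `2 * d` draws
#' from the global random stream.
#'
#' @param a Current control parameter, `>= 0`.
#' @param d Dimension (feature count).
#' @return A list with components `A` (in `[-a, a]^d`) and `C` (in
#'   `[0, 2]^d`).
#' @export
draw_coefficients <- function(a, d) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a < 0) {
    stop("`a` must be a single finite number >= 0", call. = FALSE)
  }
  list(
    A = 2 * a * stats::runif(d) - a,
    C = 2 * stats::runif(d)
  )
}

#' Leader-guided continuous position update
#'
#' The core grey-wolf move: a wolf at (binary) position `x` is pulled toward
#' the three current leaders. For each leader \eqn{L \in \{\alpha, \beta,
#' \delta\}} an independent coefficient pair is drawn, the randomized
#' distance \eqn{D_L = |C_L X_L - x|} is formed, a guide point
#' \eqn{X_L - A_L D_L} is computed, and the new continuous position is the
#' mean of the three guide points. All arithmetic is element-wise.
#'
#' @param x Numeric vector, the wolf's current (binary) position.
#' @param alpha,beta,delta Numeric vectors, the three leader positions; all
#'   the same length as `x`.
#' @param a Current control parameter.
#' @return Numeric vector: the new continuous position (binarize it with
#'   [binarize()] to obtain the new mask).
#' @export
leader_guided_position <- function(x, alpha, beta, delta, a) {
  d <- length(x)
  if (length(alpha) != d || length(beta) != d || length(delta) != d) {
    stop("position and leader vectors must all have the same length",
         call. = FALSE)
  }
  guide <- function(leader) {
    cf <- draw_coefficients(a, d)
    leader - cf$A * abs(cf$C * leader - x)
  }
  (guide(alpha) + guide(beta) + guide(delta)) / 3
}

#' Sort a population by fitness and split into masters and slaves
#'
#' Sorts an even-sized population in ascending order of fitness (lower is
#' better) with a stable sort, so equal fitnesses keep their prior order.
#' The fitter top half become master wolves, the bottom half slave wolves.
#'
#' @param fitness Numeric vector of evaluated fitnesses, even length.
#' @return A list with `order` (permutation sorting the population),
#'   `masters` and `slaves` (original indices of each half, in sorted
#'   order).
#' @export
rank_and_split <- function(fitness) {
  n <- length(fitness)
  if (n %% 2L != 0L || n < 2L) {
    stop("population size must be even and >= 2", call. = FALSE)
  }
  if (any(!is.finite(fitness))) {
    stop("all wolves must have finite evaluated fitness", call. = FALSE)
  }
  ord <- order(fitness)  # radix sort on doubles: stable, ties keep order
  half <- n %/% 2L
  list(order = ord, masters = ord[seq_len(half)], slaves = ord[half + seq_len(half)])
}

#' Master-slave index pairing
#'
#' For an even population of `n` wolves sorted by fitness, slave \eqn{S} is
#' paired with master \eqn{M} by \eqn{S = M + n/2}, for \eqn{M = 1, \dots,
#' n/2}. Every wolf appears in exactly one pair: the best wolf teaches the
#' median wolf, the median master teaches the worst slave, and so on.
#'
#' @param n Population size, even and `>= 2`.
#' @return An `n/2 x 2` integer matrix with columns `master` and `slave`
#'   (1-based positions in the sorted population).
#' @examples
#' pair_master_slave(10)
#' @export
pair_master_slave <- function(n) {
  if (length(n) != 1L || n < 2L || n %% 2L != 0L) {
    stop("`n` must be a single even integer >= 2", call. = FALSE)
  }
  half <- as.integer(n) %/% 2L
  m <- seq_len(half)
  cbind(master = m, slave = m + half)
}

#' Master-slave learning step
#'
#' Moves a slave wolf a randomized fraction of the way toward its master:
#' the scaled distance \eqn{D_L = \omega |C_4 X_M - X_S|} is formed with a
#' fresh coefficient pair, the continuous target is \eqn{X_n = X_M - A_4
#' D_L}, and the result is binarized with per-dimension random thresholds.
#' The learning coefficient \eqn{\omega \in [0, 1]} sets how far the slave
#' strays from the master's position: small \eqn{\omega} keeps slaves close
#' to (diversified copies of) the masters. The returned mask replaces the
#' slave's old position unconditionally; there is no accept-if-better guard.
#'
#' @param master,slave Numeric vectors, the two binary positions.
#' @param omega Learning coefficient in `[0, 1]`.
#' @param a Current control parameter.
#' @return Integer 0/1 vector: the slave's new mask.
#' @export
slave_learning_step <- function(master, slave, omega, a) {
  d <- length(master)
  if (length(slave) != d) {
    stop("`master` and `slave` must have the same length", call. = FALSE)
  }
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0 || omega > 1) {
    stop("`omega` must be a single number in [0, 1]", call. = FALSE)
  }
  cf <- draw_coefficients(a, d)
  d_l <- omega * abs(cf$C * master - slave)
  x_n <- master - cf$A * d_l
  binarize(x_n, threshold = "random")
}

## Best-so-far leader bookkeeping: leaders are historical snapshots
## (mask + fitness), retained across iterations until beaten.
update_leaders <- function(leaders, mask, fitness) {
  if (fitness < leaders$alpha$fitness) {
    leaders$delta <- leaders$beta
    leaders$beta  <- leaders$alpha
    leaders$alpha <- list(mask = mask, fitness = fitness)
  } else if (fitness < leaders$beta$fitness) {
    leaders$delta <- leaders$beta
    leaders$beta  <- list(mask = mask, fitness = fitness)
  } else if (fitness < leaders$delta$fitness) {
    leaders$delta <- list(mask = mask, fitness = fitness)
  }
  leaders
}

#' Run the binary grey wolf optimizer
#'
#' The population engine shared by MSBGWO and BGWO2. Each iteration: (i) the
#' control parameter `a` is computed from the variant's schedule (nonlinear
#' for MSBGWO, linear for BGWO2); (ii) every wolf takes a leader-guided step
#' and is binarized with the fixed 0.5 threshold; (iii) every wolf is
#' (re-)evaluated and the best-so-far leaders are updated; (iv) for MSBGWO
#' only, the population is sorted, split into master and slave halves, each
#' slave learns from its paired master (random-threshold binarization) and
#' is re-evaluated immediately. The best mask ever observed is returned
#' together with the per-iteration best-so-far convergence series, which is
#' non-increasing by construction.
#'
#' Initial masks are independent Bernoulli(0.5) bits; an all-zero initial
#' mask (an empty feature subset, on which the fitness is undefined) is
#' re-drawn. During the run, empty masks produced by binarization are kept
#' in the population but scored with a sentinel worst fitness by the
#' evaluator, so the dynamics continue without special-casing.
#'
#' All randomness is taken from R's global stream; `seed` (if non-NULL) is
#' applied once at entry, making runs exactly replayable.
#'
#' @param evaluate Fitness callback: takes an integer 0/1 mask, returns a
#'   list with at least `fitness` (lower is better). See
#'   [make_knn_evaluator()].
#' @param n_features Dimension of the search space (feature count).
#' @param variant `"msbgwo"` or `"bgwo2"`.
#' @param pop_size Population size `N`, even and `>= 2` (default 10).
#' @param iterations Iteration budget `T` (default 100).
#' @param omega Master-slave learning coefficient (default 0.1); ignored by
#'   BGWO2.
#' @param seed Optional integer seed.
#' @return A list of class `"gwo_trace"`: `best_mask`, `best_fitness`,
#'   `convergence` (length `iterations`), `variant`, `n_evaluations`, and
#'   `population` (final masks as a matrix).
#' @export
run_gwo <- function(evaluate, n_features,
                    variant = c("msbgwo", "bgwo2"),
                    pop_size = 10L, iterations = 100L,
                    omega = 0.1, seed = NULL) {
  variant <- match.arg(variant)
  if (pop_size < 2L || pop_size %% 2L != 0L) {
    stop("`pop_size` must be even and >= 2", call. = FALSE)
  }
  if (iterations < 1L) stop("`iterations` must be >= 1", call. = FALSE)
  if (n_features < 2L) stop("`n_features` must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  schedule <- if (variant == "msbgwo") "nonlinear" else "linear"

  # Bernoulli(0.5) init; empty subsets re-drawn (fitness undefined there)
  pop <- lapply(seq_len(pop_size), function(i) {
    repeat {
      m <- as.integer(stats::runif(n_features) < 0.5)
      if (sum(m) > 0L) return(m)
    }
  })
  n_eval <- 0L
  fit <- numeric(pop_size)
  for (i in seq_len(pop_size)) {
    fit[i] <- evaluate(pop[[i]])$fitness
    n_eval <- n_eval + 1L
  }

  worst <- list(mask = pop[[1L]], fitness = Inf)
  leaders <- list(alpha = worst, beta = worst, delta = worst)
  for (i in order(fit)[seq_len(min(3L, pop_size))]) {
    leaders <- update_leaders(leaders, pop[[i]], fit[i])
  }

  convergence <- numeric(iterations)
  for (t in seq_len(iterations)) {
    a <- control_param(t, iterations, schedule)

    # leaders stay fixed for the whole sweep (reference GWO convention);
    # best-so-far merge happens after every wolf has moved
    la <- leaders$alpha$mask
    lb <- leaders$beta$mask
    ld <- leaders$delta$mask
    for (i in seq_len(pop_size)) {
      xn <- leader_guided_position(pop[[i]], la, lb, ld, a)
      pop[[i]] <- binarize(xn, threshold = "half")
      fit[i] <- evaluate(pop[[i]])$fitness
      n_eval <- n_eval + 1L
    }
    for (i in seq_len(pop_size)) {
      leaders <- update_leaders(leaders, pop[[i]], fit[i])
    }

    if (variant == "msbgwo") {
      rs <- rank_and_split(fit)
      pop <- pop[rs$order]
      fit <- fit[rs$order]
      pairs <- pair_master_slave(pop_size)
      for (p in seq_len(nrow(pairs))) {
        m_idx <- pairs[p, "master"]
        s_idx <- pairs[p, "slave"]
        pop[[s_idx]] <- slave_learning_step(pop[[m_idx]], pop[[s_idx]],
                                            omega, a)
        fit[s_idx] <- evaluate(pop[[s_idx]])$fitness
        n_eval <- n_eval + 1L
        leaders <- update_leaders(leaders, pop[[s_idx]], fit[s_idx])
      }
    }

    convergence[t] <- leaders$alpha$fitness
  }

  structure(list(
    best_mask = leaders$alpha$mask,
    best_fitness = leaders$alpha$fitness,
    convergence = convergence,
    variant = variant,
    n_evaluations = n_eval,
    population = do.call(rbind, pop)
  ), class = "gwo_trace")
}
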