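#' Sigmoid transfer function for binarization
#'
#' Maps a continuous wolf coordinate to an inclusion probability through the
#' steep sigmoid \eqn{S(x) = 1 / (1 + e^{-10 (x - 0.5)})}. The slope (10) and
#' shift (0.5) are fixed constants of the binary encoding, not tunables: they
#' centre the transfer on 0.5 so that a coordinate of 0.5 is maximally
#' undecided, and make the transition sharp enough that coordinates near 0 or
#' 1 map almost deterministically.
#'
#' @param x Numeric vector of continuous coordinates; every entry must be
#'   finite.
#' @return Numeric vector of the same length with entries in the open
#'   interval (0, 1).
#' @examples
#' sigmoid_transfer(0.5)          # exactly 0.5
#' sigmoid_transfer(c(-1, 0, 1))  # steeply increasing
#' @export
sigmoid_transfer <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop("`x` must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("`x` contains non-finite values", call. = FALSE)
  }
  1 / (1 + exp(-10 * (x - 0.5)))
}

#' Binarize a continuous wolf position
#'
#' Converts a continuous position into a 0/1 feature mask: bit \eqn{d} is 1
#' iff \eqn{S(x_d) > \theta_d}, with `sigmoid_transfer` as \eqn{S}. The
#' threshold is either one independent uniform(0,1) draw per dimension
#' (`"random"`, used in the master-slave learning step, where the stochastic
#' threshold preserves exploration) or the constant 0.5 (`"half"`, used for
#' the whole-population leader update, making that phase deterministic given
#' the continuous positions). The inequality is strict, so an exact tie maps
#' to 0.
#'
#' In `"random"` mode the function consumes `length(pos)` draws from R's
#' global random stream; seed the session for reproducibility.
#'
#' @param pos Numeric vector, the continuous position (finite entries).
#' @param threshold `"half"` for the fixed 0.5 threshold or `"random"` for
#'   per-dimension uniform draws.
#' @return Integer vector of 0s and 1s, same length as `pos`.
#' @examples
#' binarize(c(10, -10, 0.5), threshold = "half")  # 1, 0, 0
#' @export
binarize <- function(pos, threshold = c("half", "random")) {
  threshold <- match.arg(threshold)
  s <- sigmoid_transfer(pos)
  thr <- switch(threshold,
    half   = rep.int(0.5, length(pos)),
    random = stats::runif(length(pos))
  )
  as.integer(s > thr)
}
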