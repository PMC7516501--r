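#' Binomial thinning
#'
#' The integer analogue of scalar multiplication in autoregressions:
#' \eqn{\alpha \circ Y} is a sum of `Y` independent Bernoulli(\eqn{\alpha})
#' variables, i.e. a Binomial(`Y`, \eqn{\alpha}) draw (0 when `Y = 0`).
#'
#' @param alpha thinning probability in `[0, 1]`.
#' @param count non-negative integer count (vectorized).
#' @return Integer vector of the same length as `count`.
#' @examples
#' set.seed(1); binomial_thinning(0.15, c(10, 0, 4))
#' @export
binomial_thinning <- function(alpha, count) {
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha must lie in [0, 1]")
  if (any(count < 0) || any(count != round(count))) {
    stop("count must be a non-negative integer")
  }
  rbinom(length(count), size = as.integer(count), prob = alpha)
}

#' Finite Poisson mixture specification for the innovations
#'
#' Describes innovations drawn as \eqn{Z_t \sim \mathrm{Poisson}(r_j)} with
#' component `j` picked with probability `weights[j]`.  The default is the
#' benchmark design used throughout the package's examples: an equal-weight
#' mixture of Poisson(1), Poisson(8) and Poisson(15).
#'
#' @param weights mixture weights (normalized if needed, must be
#'   non-negative and sum to a positive value).
#' @param rates positive Poisson rates, one per component.
#' @return An object of class `mixture_innovations`.
#' @export
mixture_innovations <- function(weights = rep(1 / 3, 3), rates = c(1, 8, 15)) {
  if (length(weights) != length(rates)) {
    stop("weights and rates must have equal length")
  }
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid mixture weights")
  if (any(rates <= 0)) stop("mixture rates must be positive")
  structure(list(weights = weights / sum(weights), rates = rates),
            class = "mixture_innovations")
}

#' Simulate a generalized INAR(p) series
#'
#' Simulates \eqn{Y_t = \alpha_1 \circ Y_{t-1} + \dots + \alpha_p \circ
#' Y_{t-p} + Z_t}.  Innovations are either drawn from a finite Poisson
#' mixture ([mixture_innovations()]) — in which case the latent component of
#' each \eqn{Z_t} is recorded so cluster recovery can later be scored — or
#' taken as Poisson with user-supplied per-epoch rates.
#'
#' @param alpha vector of thinning probabilities \eqn{(\alpha_1, \dots,
#'   \alpha_p)}, each in `[0, 1]`.  If they sum to 1 or more the process is
#'   explosive; a warning is issued but simulation proceeds.
#' @param innovations a [mixture_innovations()] object, or a numeric vector
#'   of positive rates \eqn{\lambda_{p+1}, \dots, \lambda_T}.
#' @param T series length (must exceed `length(alpha)`).
#' @param init optional integer vector of initial counts
#'   \eqn{y_1, \dots, y_p}; by default drawn as Poisson with mean
#'   (mean innovation rate)/(1 - sum(alpha)) (its stationary mean when
#'   non-explosive, the mean innovation rate otherwise).
#' @return A list with `series` (a [count_series()]), `rates` (the true
#'   \eqn{\lambda_t}, epochs `p+1..T`) and `components` (integer mixture
#'   component per epoch, or `NULL` for explicit rates).
#' @examples
#' set.seed(42)
#' sim <- simulate_inar(0.15, mixture_innovations(), T = 200)
#' table(sim$components)
#' @export
simulate_inar <- function(alpha, innovations = mixture_innovations(),
                          T = 1000L, init = NULL) {
  p <- length(alpha)
  if (p < 1L) stop("alpha must have at least one element")
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha entries must lie in [0, 1]")
  if (sum(alpha) >= 1) {
    warning("sum(alpha) >= 1: the simulated process is explosive")
  }
  T <- as.integer(T)
  if (T <= p) stop("T must exceed the order p")
  n <- T - p

  if (inherits(innovations, "mixture_innovations")) {
    comp <- sample.int(length(innovations$rates), n, replace = TRUE,
                       prob = innovations$weights)
    rates <- innovations$rates[comp]
  } else {
    rates <- as.numeric(innovations)
    if (length(rates) == 1L) rates <- rep(rates, n)
    if (length(rates) != n) {
      stop("innovation rates must have length T - p (or 1)")
    }
    if (any(rates <= 0)) stop("innovation rates must be positive")
    comp <- NULL
  }

  if (is.null(init)) {
    mu <- mean(rates) / max(1 - sum(alpha), 1e-12)
    if (sum(alpha) >= 1) mu <- mean(rates)
    init <- rpois(p, mu)
  }
  if (length(init) != p || any(init < 0) || any(init != round(init))) {
    stop("init must be p non-negative integers")
  }

  y <- integer(T)
  y[seq_len(p)] <- as.integer(init)
  z <- rpois(n, rates)
  for (t in (p + 1):T) {
    surv <- sum(rbinom(p, size = y[t - seq_len(p)], prob = alpha))
    y[t] <- surv + z[t - p]
  }
  list(series = count_series(y, order = p),
       rates = rates, components = comp)
}
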