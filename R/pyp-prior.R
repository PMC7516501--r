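#' Pitman-Yor process hyperparameters
#'
#' The Pitman-Yor process \eqn{PY(\tau, \sigma, G_0)} is the two-parameter
#' generalization of the Dirichlet process: \eqn{0 \le \sigma < 1} is the
#' discount parameter, \eqn{\tau > -\sigma} the concentration parameter, and
#' here the base measure \eqn{G_0} is a Gamma distribution with shape `a0`
#' and rate `b0` from which new innovation-rate atoms are drawn.
#'
#' @param tau concentration parameter, `tau > -sigma`.
#' @param sigma discount parameter in `[0, 1)`; `sigma = 0` recovers the
#'   Dirichlet process.
#' @param a0,b0 shape and rate of the Gamma base measure, both positive.
#' @return An object of class `py_hyperparams` (a validated list).
#' @examples
#' py_hyperparams(tau = 1, sigma = 0.5, a0 = 2, b0 = 0.5)
#' @export
py_hyperparams <- function(tau, sigma = 0, a0 = 1, b0 = 1) {
  check_py_params(tau, sigma)
  if (!is.numeric(a0) || length(a0) != 1L || a0 <= 0 ||
      !is.numeric(b0) || length(b0) != 1L || b0 <= 0) {
    stop("base-measure parameters a0 and b0 must be positive")
  }
  structure(list(tau = tau, sigma = sigma, a0 = a0, b0 = b0),
            class = "py_hyperparams")
}

check_py_params <- function(tau, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0 || sigma >= 1) {
    stop("discount parameter sigma must lie in [0, 1)")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= -sigma) {
    stop("concentration parameter tau must exceed -sigma")
  }
  invisible(TRUE)
}

#' @export
print.py_hyperparams <- function(x, ...) {
  cat(sprintf(
    "Pitman-Yor hyperparameters: tau = %.4g, sigma = %.4g, G0 = Gamma(a0 = %.4g, b0 = %.4g)\n",
    x$tau, x$sigma, x$a0, x$b0))
  invisible(x)
}

#' Pitman-Yor posterior predictive weights
#'
#' Given `n` previously observed values, the next draw from a
#' \eqn{PY(\tau, \sigma, G_0)} sample is new (from \eqn{G_0}) with
#' probability \eqn{(\tau + k\sigma)/(\tau + n)}, where `k` is the number of
#' distinct observed values, or repeats the i-th observation with
#' probability \eqn{(1 - \sigma/n_i)/(\tau + n)}, where \eqn{n_i} is the
#' multiplicity of that observation's value.  The weights always sum to one.
#'
#' @param hyper a [py_hyperparams()] object.
#' @param values the previously observed values (ties define the
#'   multiplicities).
#' @return A list with `new_value_weight` (scalar) and `obs_weights`
#'   (one weight per element of `values`).
#' @examples
#' h <- py_hyperparams(tau = 0.5, sigma = 0.5)
#' py_predictive_weights(h, values = 3.2)  # new 2/3, repeat 1/3
#' @export
py_predictive_weights <- function(hyper, values) {
  stopifnot(inherits(hyper, "py_hyperparams"))
  n <- length(values)
  if (n < 1L) stop("need at least one prior observation")
  mult <- table(match(values, unique(values)))
  n_i <- as.numeric(mult)[match(values, unique(values))]
  k <- length(unique(values))
  new_w <- (hyper$tau + k * hyper$sigma) / (hyper$tau + n)
  obs_w <- (1 - hyper$sigma / n_i) / (hyper$tau + n)
  list(new_value_weight = new_w, obs_weights = obs_w)
}

# Log generalized factorial coefficients log C(n, k; sigma) for k = 1..n,
# via the triangular recurrence
#   C(n+1, k) = (n - k sigma) C(n, k) + sigma C(n, k-1),  C(1, 1) = sigma.
# For 0 < sigma < 1 and k <= n every term is non-negative; a negative factor
# would signal a broken recurrence and raises.  For sigma = 0 the rescaled
# coefficients C(n, k; sigma)/sigma^k reduce to unsigned Stirling numbers of
# the first kind, handled by log_stirling1_row().
log_gfc_row <- function(n, sigma) {
  stopifnot(n >= 1, sigma > 0, sigma < 1)
  lc <- -Inf
  lc[1] <- log(sigma)                  # row n = 1
  if (n == 1L) return(lc)
  for (m in 1:(n - 1)) {               # build row m+1 from row m
    new <- rep(-Inf, m + 1L)
    fac <- m - (1:m) * sigma
    if (any(fac < 0)) stop("negative factor in the triangular recurrence")
    stay <- log(fac) + lc[1:m]
    up <- log(sigma) + c(-Inf, lc[1:m])[1:(m + 1L)]
    stay <- c(stay, -Inf)
    new <- pmax(stay, up) + log1p(exp(-abs(stay - up)))
    new[!is.finite(stay) & !is.finite(up)] <- -Inf
    lc <- new
  }
  lc
}

# log of unsigned Stirling numbers of the first kind |s(n, k)|, k = 1..n:
#   |s(n+1, k)| = n |s(n, k)| + |s(n, k-1)|.
log_stirling1_row <- function(n) {
  stopifnot(n >= 1)
  lc <- 0                              # |s(1,1)| = 1
  if (n == 1L) return(lc)
  for (m in 1:(n - 1)) {
    stay <- c(log(m) + lc, -Inf)
    up <- c(-Inf, lc)
    new <- pmax(stay, up) + log1p(exp(-abs(stay - up)))
    new[!is.finite(stay) & !is.finite(up)] <- -Inf
    lc <- new
  }
  lc
}

#' Prior distribution of the number of clusters under a Pitman-Yor process
#'
#' For `n` exchangeable draws from \eqn{PY(\tau, \sigma, G_0)} with a
#' diffuse base measure, the number of distinct values `K` has
#' \deqn{\Pr\{K = k\} = \frac{\prod_{i=1}^{k-1}(\tau + i\sigma)}
#'   {\sigma^k (\tau+1)_{n-1}} \, C(n, k; \sigma),}
#' where \eqn{(x)_n = \Gamma(x+n)/\Gamma(x)} is the rising factorial and
#' \eqn{C(n,k;\sigma)} the generalized factorial coefficient.  For
#' \eqn{\sigma = 0} the Dirichlet-process limit
#' \eqn{\Pr\{K=k\} = |s(n,k)| \tau^k / (\tau)_n} (unsigned Stirling numbers
#' of the first kind) is used.  All computation is in log space.
#'
#' @param n number of draws, a positive integer.
#' @param tau,sigma Pitman-Yor concentration and discount parameters.
#' @return A probability vector of length `n` over `k = 1..n`.
#' @examples
#' num_clusters_pmf(2, tau = 1, sigma = 0.25)  # (1-sigma)/(tau+1), (tau+sigma)/(tau+1)
#' @export
num_clusters_pmf <- function(n, tau, sigma = 0) {
  check_py_params(tau, sigma)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (n == 1L) return(1)
  k <- 1:n
  if (sigma > 0) {
    lnum <- cumsum(c(0, log(tau + (1:(n - 1)) * sigma)))  # sum_{i<k} log(tau+i*sigma)
    lp <- lnum - k * log(sigma) -
      (lgamma(tau + n) - lgamma(tau + 1)) + log_gfc_row(n, sigma)
  } else {
    if (tau <= 0) stop("sigma = 0 requires tau > 0")
    lp <- k * log(tau) - (lgamma(tau + n) - lgamma(tau)) + log_stirling1_row(n)
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Prior expected number of clusters under a Pitman-Yor process
#'
#' Closed forms: \eqn{E[K] = \tau\{\psi(\tau+n) - \psi(\tau)\}} for
#' \eqn{\sigma = 0} (with \eqn{\psi} the digamma function) and
#' \eqn{E[K] = (\tau+\sigma)_n / \{\sigma (\tau+1)_{n-1}\} - \tau/\sigma}
#' for \eqn{\sigma > 0}, with rising factorials evaluated through
#' `lgamma` to avoid overflow.
#'
#' @inheritParams num_clusters_pmf
#' @return The scalar \eqn{E[K]}, between 1 and `n`.
#' @examples
#' expected_num_clusters(tau = 1, sigma = 0.5, n = 100)
#' @export
expected_num_clusters <- function(tau, sigma = 0, n) {
  check_py_params(tau, sigma)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (n == 1L) return(1)
  if (sigma > 0) {
    lr <- (lgamma(tau + sigma + n) - lgamma(tau + sigma)) -
      (lgamma(tau + n) - lgamma(tau + 1))
    exp(lr - log(sigma)) - tau / sigma
  } else {
    if (tau <= 0) stop("sigma = 0 requires tau > 0")
    tau * (digamma(tau + n) - digamma(tau))
  }
}

#' Solve for the concentration parameter given a prior cluster expectation
#'
#' Finds `tau` such that the prior expected number of clusters among `n`
#' Pitman-Yor draws equals `k0`, by bisection on \eqn{(-\sigma, \infty)}
#' (where \eqn{E[K]} is strictly increasing in `tau`).
#'
#' @param k0 target prior expectation of the number of clusters,
#'   `1 < k0 < n`.
#' @param sigma discount parameter in `[0, 1)`.
#' @param n number of Pitman-Yor draws (for a PY-INAR(p) fit, `T - p`).
#' @param tol absolute tolerance on \eqn{E[K] - k_0}.
#' @return The solving `tau` (> -sigma).
#' @examples
#' tau <- solve_tau(k0 = 10, sigma = 0.5, n = 999)
#' expected_num_clusters(tau, 0.5, 999)
#' @export
solve_tau <- function(k0, sigma = 0, n, tol = 1e-8) {
  if (!is.numeric(k0) || length(k0) != 1L || k0 <= 1) {
    stop("k0 must exceed 1 (E[K] > 1 requires tau > the tau -> -sigma limit)")
  }
  n <- as.integer(n)
  if (k0 >= n) {
    stop(sprintf("k0 = %.3g is not attainable: E[K] < n = %d for finite tau",
                 k0, n))
  }
  eps <- 1e-10
  lo <- -sigma + eps
  if (sigma == 0) lo <- eps
  f <- function(tau) expected_num_clusters(tau, sigma, n) - k0
  flo <- f(lo)
  if (flo > 0) {
    stop(sprintf(
      "k0 = %.3g is below the attainable range: E[K] >= %.4g for sigma = %.3g, n = %d",
      k0, flo + k0, sigma, n))
  }
  hi <- max(1, -sigma + 1)
  while (f(hi) < 0) {
    hi <- 2 * hi + 1
    if (hi > 1e12) stop("k0 outside the attainable range of E[K]")
  }
  uniroot(f, lower = lo, upper = hi, tol = tol / 10)$root
}

#' Kullback-Leibler divergence from a uniform reference to the Gamma base
#' measure
#'
#' The divergence \eqn{KL(\mathrm{Unif}[0, \lambda_{max}] \,\|\,
#' \mathrm{Gamma}(a_0, b_0))} in closed form:
#' \deqn{-\log\lambda_{max} - a_0\log b_0 + \log\Gamma(a_0)
#'   - (a_0 - 1)(\log\lambda_{max} - 1) + b_0\lambda_{max}/2.}
#' Used to re-parameterize the base measure by a single spread scale
#' `lambda_max`.
#'
#' @param a0,b0 Gamma shape and rate, positive.
#' @param lambda_max width of the uniform reference distribution, positive.
#' @return The divergence (a finite real, non-negative).
#' @export
kl_uniform_gamma <- function(a0, b0, lambda_max) {
  if (any(c(a0, b0, lambda_max) <= 0)) {
    stop("a0, b0 and lambda_max must all be positive")
  }
  -log(lambda_max) - a0 * log(b0) + lgamma(a0) -
    (a0 - 1) * (log(lambda_max) - 1) + b0 * lambda_max / 2
}

#' Elicit the Gamma base measure from a reference scale
#'
#' Chooses `(a0, b0)` minimizing the Kullback-Leibler divergence between a
#' uniform distribution on \eqn{[0, \lambda_{max}]} and the Gamma base
#' measure.  Stationarity in `b0` gives the profile identity
#' \eqn{b_0 = 2 a_0 / \lambda_{max}}; substituting it reduces the problem
#' to a one-dimensional minimization over `a0` (on a log scale over
#' `[1e-3, 1e3]`), whose solution does not depend on `lambda_max`.
#' The support of \eqn{G_0} is not truncated by this choice; the uniform
#' distribution is only a reference.
#'
#' @param lambda_max positive reference scale.
#' @return A list with components `a0`, `b0` and `kl` (the attained
#'   divergence).
#' @examples
#' elicit_base_measure(20)
#' @export
elicit_base_measure <- function(lambda_max) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1L || lambda_max <= 0) {
    stop("lambda_max must be a positive scalar")
  }
  prof <- function(loga) {
    a <- exp(loga)
    kl_uniform_gamma(a, 2 * a / lambda_max, lambda_max)
  }
  opt <- optimize(prof, interval = log(c(1e-3, 1e3)), tol = 1e-10)
  if (!is.finite(opt$objective)) {
    stop("base-measure elicitation failed to converge; last iterate a0 = ",
         exp(opt$minimum))
  }
  a0 <- exp(opt$minimum)
  list(a0 = a0, b0 = 2 * a0 / lambda_max, kl = opt$objective)
}

#' Elicit full Pitman-Yor hyperparameters
#'
#' Convenience wrapper combining [solve_tau()] (concentration from the prior
#' expected number of clusters `k0`) and [elicit_base_measure()] (Gamma base
#' measure from the reference scale `lambda_max`).
#'
#' @inheritParams solve_tau
#' @param lambda_max reference scale for the base measure.
#' @return A [py_hyperparams()] object.
#' @export
elicit_hyperparams <- function(k0, sigma, lambda_max, n) {
  base <- elicit_base_measure(lambda_max)
  tau <- solve_tau(k0, sigma, n)
  py_hyperparams(tau = tau, sigma = sigma, a0 = base$a0, b0 = base$b0)
}
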