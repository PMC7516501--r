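#' Exact log-likelihood of the generalized INAR(p) model
#'
#' Evaluates, by direct enumeration of the latent maturations, the
#' log-likelihood
#' \deqn{L_y(\alpha, \lambda) = \prod_{t=p+1}^T \sum_{m_{1,t}} \cdots
#'   \sum_{m_{p,t}} \prod_i \binom{y_{t-i}}{m_{i,t}} \alpha_i^{m_{i,t}}
#'   (1-\alpha_i)^{y_{t-i}-m_{i,t}} \;
#'   \frac{e^{-\lambda_t} \lambda_t^{y_t - m_t}}{(y_t - m_t)!},}
#' where the inner sums run over the maturation configurations compatible
#' with \eqn{m_{i,t} \le y_{t-i}} and \eqn{m_t = \sum_i m_{i,t} \le y_t}.
#' The enumeration is exponential in `p`, so this function is a correctness
#' oracle for small problems rather than a production path: it refuses
#' `p > 3` or counts above 30.
#'
#' @param y a [count_series()] (or integer vector with `order` given).
#' @param alpha thinning probabilities of length `p`.
#' @param lambda innovation rates for epochs `p+1 .. T` (recycled if
#'   scalar).
#' @param order model order when `y` is a plain vector.
#' @return The log-likelihood, a finite real (or `-Inf` for impossible
#'   configurations with `alpha` on the boundary).
#' @examples
#' loglik_direct(c(1, 1), alpha = 0.5, lambda = 1)  # == -1
#' @export
loglik_direct <- function(y, alpha, lambda, order = length(alpha)) {
  y <- as_count_series(y, order = order)
  p <- series_order(y)
  if (length(alpha) != p) stop("alpha must have length p")
  if (any(alpha < 0) || any(alpha > 1)) stop("alpha entries must lie in [0, 1]")
  T <- length(y)
  n <- T - p
  if (length(lambda) == 1L) lambda <- rep(lambda, n)
  if (length(lambda) != n) stop("lambda must have length T - p")
  if (any(lambda <= 0)) stop("lambda entries must be positive")
  if (p > 3L) stop("loglik_direct enumerates maturations: p <= 3 only")
  if (max(y) > 30L) stop("loglik_direct enumerates maturations: counts <= 30 only")

  yv <- as.integer(y)
  total <- 0
  for (s in seq_len(n)) {
    t <- p + s
    total <- total + epoch_loglik(yv[t], yv[t - seq_len(p)], alpha, lambda[s])
  }
  total
}

# log p(y_t | y_{t-1..t-p}, alpha, lambda_t) by recursive enumeration of the
# maturation vector, accumulated with log-sum-exp.
epoch_loglik <- function(yt, ylags, alpha, lam) {
  p <- length(alpha)
  terms <- numeric(0)
  recurse <- function(i, used, acc) {
    if (i > p) {
      terms[length(terms) + 1L] <<- acc + dpois(yt - used, lam, log = TRUE)
      return(invisible(NULL))
    }
    hi <- min(yt - used, ylags[i])
    for (m in 0:hi) {
      recurse(i + 1L, used + m,
              acc + dbinom(m, ylags[i], alpha[i], log = TRUE))
    }
  }
  recurse(1L, 0L, 0)
  logsumexp(terms)
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Complete-data log-likelihood of the augmented INAR(p) model
#'
#' The log of \eqn{p(y, m \mid \alpha, \lambda) = \prod_t
#' \prod_i \mathrm{Bin}(m_{i,t}; y_{t-i}, \alpha_i) \,
#' \mathrm{Pois}(y_t - m_t; \lambda_t)} for a full maturation matrix `m`.
#' Summed over all admissible maturation configurations this reproduces
#' [loglik_direct()] (the data augmentation is exact), which the test suite
#' verifies by brute force on small series.
#'
#' @inheritParams loglik_direct
#' @param m integer maturation matrix, `p` rows and `T - p` columns;
#'   `m[i, s]` is the maturation of lag `i` at epoch `p + s`.
#' @return The complete-data log-likelihood (`-Inf` for inadmissible `m`).
#' @export
loglik_augmented <- function(y, m, alpha, lambda, order = length(alpha)) {
  y <- as_count_series(y, order = order)
  p <- series_order(y)
  T <- length(y)
  n <- T - p
  m <- matrix(as.integer(m), nrow = p, ncol = n)
  if (length(lambda) == 1L) lambda <- rep(lambda, n)
  yv <- as.integer(y)
  total <- 0
  for (s in seq_len(n)) {
    t <- p + s
    mt <- sum(m[, s])
    if (mt > yv[t] || any(m[, s] < 0) || any(m[, s] > yv[t - seq_len(p)])) {
      return(-Inf)
    }
    total <- total +
      sum(dbinom(m[, s], yv[t - seq_len(p)], alpha, log = TRUE)) +
      dpois(yv[t] - mt, lambda[s], log = TRUE)
  }
  total
}
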