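# Independent oracles used across the test files.

# Brute-force INAR(p) log-likelihood: enumerate every maturation
# configuration per epoch with expand.grid (independent of the package's
# recursive log-sum-exp path).
oracle_loglik <- function(y, alpha, lambda) {
  p <- length(alpha)
  T <- length(y)
  n <- T - p
  if (length(lambda) == 1L) lambda <- rep(lambda, n)
  total <- 0
  for (s in seq_len(n)) {
    t <- p + s
    grid <- do.call(expand.grid, lapply(seq_len(p), function(i) 0:y[t - i]))
    lik <- 0
    for (r in seq_len(nrow(grid))) {
      m <- as.numeric(grid[r, ])
      if (sum(m) > y[t]) next
      term <- prod(dbinom(m, y[t - seq_len(p)], alpha)) *
        dpois(y[t] - sum(m), lambda[s])
      lik <- lik + term
    }
    total <- total + log(lik)
  }
  total
}

# Sequential Pitman-Yor urn in plain R (slow, used only at tiny sizes where
# the compiled urn would be overkill to trust blindly).
r_urn_k <- function(n, tau, sigma) {
  sizes <- 1
  for (i in seq_len(n - 1)) {
    w <- c(tau + length(sizes) * sigma, sizes - sigma)
    pick <- sample.int(length(w), 1L, prob = w / sum(w))
    if (pick == 1L) sizes <- c(sizes, 1) else sizes[pick - 1L] <- sizes[pick - 1L] + 1
  }
  length(sizes)
}

# Quadrature evaluation of KL(Uniform[0, lambda_max] || Gamma(a0, b0)).
oracle_kl <- function(a0, b0, lambda_max) {
  f <- function(x) (1 / lambda_max) *
    (log(1 / lambda_max) - dgamma(x, shape = a0, rate = b0, log = TRUE))
  integrate(f, 0, lambda_max, rel.tol = 1e-10)$value
}

# Benchmark simulation used by several suites: INAR(1), thinning 0.15,
# equal-weight Poisson(1)/Poisson(8)/Poisson(15) innovations.
benchmark_sim <- function(T = 1000L, seed = 11L) {
  set.seed(seed)
  simulate_inar(0.15, mixture_innovations(), T = T)
}

# A hand-made pyinar_fit carrying prescribed rate draws, for the cluster
# and forecast pipelines.
fake_fit <- function(lambda_draws, alpha_draws = NULL, y = NULL,
                     hyper = py_hyperparams(1, 0.5, a0 = 2, b0 = 1),
                     model = "pyinar") {
  nd <- nrow(lambda_draws)
  n <- ncol(lambda_draws)
  if (is.null(alpha_draws)) alpha_draws <- matrix(0.15, nd, 1)
  if (is.null(y)) y <- count_series(rep(1L, n + 1L), order = 1L)
  k <- apply(lambda_draws, 1, function(r) length(unique(r)))
  structure(list(
    draws = list(alpha = alpha_draws, k = k, lambda = lambda_draws,
                 loglik = rep(0, nd)),
    cocluster = NULL, y = y, hyper = hyper, model = model,
    config = list(n_iter = nd, n_burn = 0L, thin = 1L),
    final_state = NULL), class = "pyinar_fit")
}
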