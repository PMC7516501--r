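test_that("sampler output respects the state invariants", {
  sim <- benchmark_sim(T = 150, seed = 3)
  h <- elicit_hyperparams(k0 = 5, sigma = 0.5, lambda_max = 20, n = 149)
  fit <- fit_pyinar(sim$series, h, n_iter = 400, n_burn = 100, seed = 9)
  expect_equal(nrow(fit$draws$alpha), 300)
  expect_length(fit$draws$k, 300)
  expect_true(all(fit$draws$alpha > 0 & rowSums(fit$draws$alpha) < 1))
  expect_true(all(fit$draws$lambda > 0))
  expect_true(all(fit$draws$k >= 1 & fit$draws$k <= 149))
  # per retained draw, k equals the number of distinct rates
  kk <- apply(fit$draws$lambda, 1, function(r) length(unique(r)))
  expect_identical(as.integer(kk), as.integer(fit$draws$k))
  # final maturations within their box constraints
  m <- fit$final_state$m
  yv <- as.integer(sim$series)
  expect_true(all(m >= 0))
  expect_true(all(m[1, ] <= yv[1:149]))
  expect_true(all(yv[2:150] - colSums(m) >= 0))
  # thinning retains every thin-th draw
  fit2 <- fit_pyinar(sim$series, h, n_iter = 400, n_burn = 100, thin = 3,
                     seed = 9)
  expect_equal(length(fit2$draws$k), 100)
})

test_that("an all-zero series pulls the rate posterior to its conjugate limit", {
  y <- count_series(rep(0L, 60))
  # homogeneous model: lambda | y ~ Gamma(a0, b0 + n) exactly
  fit <- fit_inar(y, a0 = 2, b0 = 1, n_iter = 4000, n_burn = 500, seed = 12)
  lam <- fit$draws$lambda[, 1]
  expect_lt(abs(mean(lam) - 2 / (1 + 59)), 4 * sd(lam) / sqrt(length(lam)))
  # PY model: posterior mass sits far below the prior mean a0/b0
  h <- py_hyperparams(1, 0.5, a0 = 2, b0 = 1)
  fitp <- fit_pyinar(y, h, n_iter = 800, n_burn = 200, seed = 13)
  expect_lt(mean(fitp$draws$lambda), 0.25 * 2 / 1)
})

test_that("the sampler recovers the thinning parameter on simulated data", {
  sim <- benchmark_sim(T = 600, seed = 17)
  h <- elicit_hyperparams(k0 = 8, sigma = 0.5, lambda_max = 30, n = 599)
  fit <- fit_pyinar(sim$series, h, n_iter = 2000, n_burn = 500, seed = 18)
  a <- fit$draws$alpha[, 1]
  expect_lt(abs(mean(a) - 0.15), 3 * sd(a))
})

test_that("the homogeneous sampler recovers both parameters", {
  set.seed(19)
  sim <- simulate_inar(0.15, innovations = rep(5, 999), T = 1000)
  fit <- fit_inar(sim$series, a0 = 1, b0 = 0.2, n_iter = 1500, n_burn = 400,
                  seed = 20)
  a <- fit$draws$alpha[, 1]
  lam <- fit$draws$lambda[, 1]
  expect_lt(abs(mean(a) - 0.15), 3 * sd(a))
  expect_lt(abs(mean(lam) - 5), 3 * sd(lam))
  expect_true(all(fit$draws$k == 1))
})

test_that("successive-conditional simulation preserves the prior of alpha", {
  # Geweke-style check on a tiny model: T = 5, p = 1, flat Dirichlet prior
  # on (alpha_1; alpha_2), so alpha_1 ~ Uniform(0, 1) a priori.  Alternating
  # data simulation and posterior sweeps must leave that marginal intact.
  h <- py_hyperparams(1, 0.5, a0 = 2, b0 = 1)
  set.seed(77)
  n_cycle <- 2500
  kept <- numeric(n_cycle)
  alpha <- runif(1)
  # lambda from the Pitman-Yor urn with Gamma(2, 1) base measure
  draw_py <- function(n) {
    lam <- rgamma(1, h$a0, rate = h$b0)
    for (i in seq_len(n - 1)) {
      w <- py_predictive_weights(h, lam)
      if (runif(1) < w$new_value_weight) {
        lam <- c(lam, rgamma(1, h$a0, rate = h$b0))
      } else {
        lam <- c(lam, lam[sample.int(length(lam), 1,
                                     prob = w$obs_weights /
                                       sum(w$obs_weights))])
      }
    }
    lam
  }
  lambda <- draw_py(4)
  for (cyc in seq_len(n_cycle)) {
    y <- integer(5); y[1] <- 2L
    for (t in 2:5) {
      y[t] <- rbinom(1, y[t - 1], alpha) + rpois(1, lambda[t - 1])
    }
    fit <- fit_pyinar(count_series(y), h, n_iter = 2, n_burn = 1,
                      keep_lambda = TRUE, cocluster = FALSE,
                      init = list(alpha = alpha, lambda = lambda))
    alpha <- fit$final_state$alpha
    lambda <- fit$final_state$lambda
    kept[cyc] <- alpha
  }
  ks <- suppressWarnings(ks.test(kept, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(kept) - 0.5), 4 * sd(kept) / sqrt(n_cycle))
})

test_that("draws serialize to CSV", {
  sim <- benchmark_sim(T = 80, seed = 5)
  h <- py_hyperparams(1, 0.5, a0 = 2, b0 = 0.5)
  fit <- fit_pyinar(sim$series, h, n_iter = 200, n_burn = 100, seed = 6)
  dir <- withr::local_tempdir()
  paths <- write_draws(fit, dir)
  df <- read.csv(file.path(dir, "draws.csv"))
  expect_identical(nrow(df), 100L)
  expect_named(df, c("alpha1", "k", "loglik"))
  lam <- read.csv(file.path(dir, "lambda.csv"))
  expect_identical(dim(lam), c(100L, 79L))
})
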