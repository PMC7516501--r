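test_that("hyperparameter validation enforces the Pitman-Yor constraints", {
  expect_error(py_hyperparams(tau = -0.6, sigma = 0.5), "tau")
  expect_error(py_hyperparams(tau = 1, sigma = 1), "sigma")
  expect_error(py_hyperparams(tau = 1, sigma = -0.1), "sigma")
  expect_error(py_hyperparams(tau = 1, sigma = 0, a0 = 0), "positive")
  expect_s3_class(py_hyperparams(tau = -0.4, sigma = 0.5), "py_hyperparams")
})

test_that("predictive weights match the urn rule and always normalize", {
  # Dirichlet-process urn with tau = 1 and one prior observation: 1/2, 1/2
  w <- py_predictive_weights(py_hyperparams(1, 0), values = 7)
  expect_equal(w$new_value_weight, 0.5)
  expect_equal(w$obs_weights, 0.5)
  # direct substitution: sigma = 0.5, tau = 0.5, n = k = 1
  w <- py_predictive_weights(py_hyperparams(0.5, 0.5), values = 7)
  expect_equal(w$new_value_weight, 2 / 3)
  expect_equal(w$obs_weights, 1 / 3, tolerance = 1e-12)
  # normalization across random tie patterns
  set.seed(4)
  for (r in 1:20) {
    vals <- sample(1:4, sample(1:12, 1), replace = TRUE)
    h <- py_hyperparams(runif(1, -0.2, 5), runif(1, 0, 0.9))
    w <- py_predictive_weights(h, vals)
    expect_true(w$new_value_weight >= 0 && all(w$obs_weights >= 0))
    expect_equal(w$new_value_weight + sum(w$obs_weights), 1, tolerance = 1e-12)
  }
})

test_that("the cluster-count pmf matches its closed forms and moments", {
  expect_equal(num_clusters_pmf(1, tau = 3, sigma = 0.3), 1)
  # two-customer urn enumeration
  for (prm in list(c(1, 0.25), c(0.5, 0), c(2, 0.75))) {
    p2 <- num_clusters_pmf(2, prm[1], prm[2])
    expect_equal(p2, c((1 - prm[2]) / (prm[1] + 1),
                       (prm[1] + prm[2]) / (prm[1] + 1)), tolerance = 1e-12)
  }
  # normalization and mean identity across a (tau, sigma, n) grid
  for (n in c(5, 30, 200)) {
    for (tau in c(0.3, 2, 10)) {
      for (sigma in c(0, 0.25, 0.5, 0.9)) {
        p <- num_clusters_pmf(n, tau, sigma)
        expect_true(all(p >= 0))
        expect_equal(sum(p), 1, tolerance = 1e-10)
        expect_equal(sum(seq_len(n) * p),
                     expected_num_clusters(tau, sigma, n),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("the sigma = 0 branch is the sigma -> 0+ limit", {
  for (n in c(10, 80)) {
    for (tau in c(0.5, 3)) {
      expect_equal(num_clusters_pmf(n, tau, 1e-8),
                   num_clusters_pmf(n, tau, 0), tolerance = 1e-5)
      # mild cancellation in the sigma > 0 formula at sigma = 1e-8
      expect_equal(expected_num_clusters(tau, 1e-8, n),
                   expected_num_clusters(tau, 0, n), tolerance = 1e-5)
    }
  }
})

test_that("pmf and expectation agree with the sequential-urn Monte Carlo", {
  set.seed(21)
  reps <- 1e5
  ks <- pyinar:::.urn_num_clusters(50L, 2, 0.25, reps)
  p <- num_clusters_pmf(50, 2, 0.25)
  # chi-square goodness of fit on pooled cells with expected count >= 5
  obs <- tabulate(ks, nbins = 50)
  keep <- which(p * reps >= 5)
  o <- c(obs[keep], reps - sum(obs[keep]))
  e <- c(p[keep], 1 - sum(p[keep])) * reps
  chi <- sum((o - e)^2 / e)
  expect_gt(pchisq(chi, df = length(o) - 1, lower.tail = FALSE), 0.01)
  # E[K] within 3 standard errors (sigma > 0 branch)
  se <- sd(ks) / sqrt(reps)
  expect_lt(abs(mean(ks) - expected_num_clusters(2, 0.25, 50)), 3 * se)
  # and the sigma = 0.5 case of the closed form at n = 100
  ks2 <- pyinar:::.urn_num_clusters(100L, 1, 0.5, reps)
  se2 <- sd(ks2) / sqrt(reps)
  expect_lt(abs(mean(ks2) - expected_num_clusters(1, 0.5, 100)), 3 * se2)
  # the compiled urn agrees with a plain-R urn at tiny size
  set.seed(22)
  kr <- replicate(4000, r_urn_k(8, 1, 0.5))
  set.seed(23)
  kc <- pyinar:::.urn_num_clusters(8L, 1, 0.5, 4000L)
  expect_lt(abs(mean(kr) - mean(kc)), 4 * sd(kr) / sqrt(4000))
})

test_that("expected cluster count behaves at the boundaries", {
  expect_equal(expected_num_clusters(5, 0.5, 1), 1)
  expect_equal(expected_num_clusters(1e-10, 0, 50), 1, tolerance = 1e-6)
  expect_error(expected_num_clusters(1, 0.5, 0), "positive")
})

test_that("solve_tau round-trips and E[K] is monotone in tau", {
  k0 <- expected_num_clusters(5, 0.5, 996)
  expect_equal(solve_tau(k0, 0.5, 996), 5, tolerance = 1e-4)
  tau <- solve_tau(10, 0.5, 999)
  expect_equal(expected_num_clusters(tau, 0.5, 999), 10, tolerance = 1e-6)
  # monotonicity on a tau grid justifies bisection
  grid <- seq(-0.4, 20, length.out = 40)
  ek <- vapply(grid, expected_num_clusters, numeric(1), sigma = 0.5, n = 200)
  expect_true(all(diff(ek) > 0))
  # sigma = 0 branch round trip
  tau0 <- solve_tau(7, 0, 500)
  expect_equal(expected_num_clusters(tau0, 0, 500), 7, tolerance = 1e-6)
  expect_error(solve_tau(501, 0.5, 500), "attainable")
  expect_error(solve_tau(1, 0.5, 500), "k0")
})

test_that("the closed-form KL divergence matches quadrature and is a true KL", {
  expect_equal(kl_uniform_gamma(2, 1, 5), oracle_kl(2, 1, 5),
               tolerance = 1e-6)
  for (a0 in c(0.5, 1.5, 4)) {
    for (b0 in c(0.2, 1, 3)) {
      for (lm in c(1, 10)) {
        kl <- kl_uniform_gamma(a0, b0, lm)
        expect_gte(kl, -1e-12)
        expect_equal(kl, oracle_kl(a0, b0, lm), tolerance = 1e-6)
      }
    }
  }
  expect_error(kl_uniform_gamma(-1, 1, 5), "positive")
})

test_that("base-measure elicitation satisfies the stationarity identity", {
  e <- elicit_base_measure(20)
  expect_equal(e$b0, 2 * e$a0 / 20, tolerance = 1e-4)
  # local minimizer: no grid perturbation improves the divergence
  for (da in c(-0.05, 0.05)) {
    for (db in c(-0.05, 0.05)) {
      expect_gte(kl_uniform_gamma(e$a0 * (1 + da), e$b0 * (1 + db), 20),
                 e$kl - 1e-10)
    }
  }
  # the optimal shape does not depend on lambda_max (scaling property)
  e1 <- elicit_base_measure(1)
  e10 <- elicit_base_measure(10)
  expect_equal(e1$a0, e10$a0, tolerance = 1e-6)
  expect_equal(e10$b0, e1$b0 / 10, tolerance = 1e-6)
})
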