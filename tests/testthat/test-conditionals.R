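test_that("grouped and per-observation lambda updates define the same kernel", {
  set.seed(41)
  for (r in 1:25) {
    h <- py_hyperparams(runif(1, -0.2, 4), runif(1, 0, 0.9),
                        a0 = runif(1, 0.5, 4), b0 = runif(1, 0.1, 2))
    atoms <- runif(sample(1:6, 1), 0.2, 12)
    sizes <- sample(1:8, length(atoms), replace = TRUE)
    resid <- sample(0:20, 1)
    grouped <- lambda_conditional_weights(resid, atoms, sizes, h,
                                          grouped = TRUE)
    flat <- lambda_conditional_weights(resid, rep(atoms, sizes), hyper = h,
                                       grouped = FALSE)
    expect_equal(grouped$prob_new, flat$prob_new, tolerance = 1e-12)
    agg <- tapply(flat$prob_atoms, rep(seq_along(atoms), sizes), sum)
    expect_equal(unname(as.numeric(agg)), grouped$prob_atoms,
                 tolerance = 1e-12)
  }
})

test_that("the omitted common factorial cancels on normalization", {
  # weights computed with the 1/(y_t - m_t)! factor restored must be
  # identical after normalization
  h <- py_hyperparams(1.3, 0.4, a0 = 2, b0 = 0.7)
  atoms <- c(0.8, 5, 11); sizes <- c(4, 2, 7); resid <- 9
  w <- lambda_conditional_weights(resid, atoms, sizes, h)
  lfac <- lgamma(resid + 1)
  lw_new <- log(h$tau + 3 * h$sigma) + h$a0 * log(h$b0) +
    lgamma(resid + h$a0) - lgamma(h$a0) -
    (resid + h$a0) * log(h$b0 + 1) - lfac
  lw_atoms <- log(sizes - h$sigma) + resid * log(atoms) - atoms - lfac
  full <- exp(c(lw_new, lw_atoms)); full <- full / sum(full)
  expect_equal(full[1], w$prob_new, tolerance = 1e-12)
  expect_equal(full[-1], w$prob_atoms, tolerance = 1e-12)
})

test_that("the lambda conditional reduces correctly in limiting cases", {
  # sigma = 0: fresh-draw weight is tau times the negative-binomial marginal
  h <- py_hyperparams(2, 0, a0 = 1.5, b0 = 1)
  w <- lambda_conditional_weights(3, atoms = 4, sizes = 5, h)
  marg <- h$b0^h$a0 * gamma(3 + h$a0) /
    (gamma(h$a0) * (h$b0 + 1)^(3 + h$a0))
  raw <- c(2 * marg, 5 * 4^3 * exp(-4))
  expect_equal(w$prob_new, raw[1] / sum(raw), tolerance = 1e-12)
  # no other observations: always a fresh Gamma(y - m + a0, b0 + 1) draw
  w1 <- lambda_conditional_weights(6, atoms = numeric(0), sizes = numeric(0),
                                   hyper = h)
  expect_equal(w1$prob_new, 1)
  expect_equal(w1$gamma_shape, 6 + h$a0)
  expect_equal(w1$gamma_rate, h$b0 + 1)
  set.seed(2)
  d <- replicate(200, sample_lambda_t(6, numeric(0), numeric(0), h))
  expect_true(all(d > 0))
  expect_lt(abs(mean(d) - (6 + h$a0) / (h$b0 + 1)),
            4 * sd(d) / sqrt(200))
})

test_that("truncated-Beta draws stay in support and match rejection sampling", {
  set.seed(43)
  x <- rtbeta(1e5, 3, 5, bound = 0.6)
  expect_true(all(x > 0 & x < 0.6))
  # rejection-sampling reference at the same parameters
  ref <- numeric(0)
  while (length(ref) < 2e4) {
    cand <- rbeta(4e4, 3, 5)
    ref <- c(ref, cand[cand < 0.6])
  }
  ks <- suppressWarnings(ks.test(x[1:2e4], ref[1:2e4]))
  expect_gt(ks$p.value, 0.001)
})

test_that("sample_alpha keeps the thinning vector in the non-explosive region", {
  set.seed(44)
  y <- count_series(sample(0:6, 40, replace = TRUE), order = 2)
  m <- matrix(0L, 2, 38)
  alpha <- c(0.2, 0.2)
  for (r in 1:200) {
    alpha <- sample_alpha(alpha, m, y)
    expect_true(all(alpha > 0) && sum(alpha) < 1)
  }
})

test_that("the maturation conditional matches its exact enumeration", {
  expect_equal(maturation_pmf(5, 0, 0, 0.4, 2), 1)        # y_{t-i} = 0
  expect_equal(maturation_pmf(5, 4, 0, 0, 2), c(1, 0, 0, 0, 0))  # alpha = 0
  set.seed(45)
  pr <- maturation_pmf(7, 5, 1, 0.35, 2.5)
  expect_equal(sum(pr), 1)
  draws <- replicate(4e4, sample_maturation(7, 5, 1, 0.35, 2.5))
  obs <- tabulate(draws + 1L, nbins = length(pr))
  chi <- sum((obs - 4e4 * pr)^2 / (4e4 * pr))
  expect_gt(pchisq(chi, df = length(pr) - 1, lower.tail = FALSE), 0.001)
})

test_that("cluster refresh keeps the partition and targets the right Gamma", {
  h <- py_hyperparams(1, 0.5, a0 = 2, b0 = 1)
  lambda <- c(3, 3, 7, 3, 7)
  resid <- c(2, 4, 6, 1, 3)
  set.seed(46)
  out <- refresh_cluster_values(lambda, resid, h)
  expect_identical(match(out, unique(out)), match(lambda, unique(lambda)))
  # single-member cluster: same law as a fresh draw, Gamma(a0 + y', b0 + 1)
  draws <- replicate(4e4, refresh_cluster_values(5, 4, h))
  expect_lt(abs(mean(draws) - (2 + 4) / (1 + 1)), 4 * sd(draws) / sqrt(4e4))
  # posterior mean of a shared atom: (a0 + sum resid)/(b0 + nu)
  draws2 <- replicate(4e4, refresh_cluster_values(c(3, 3), c(2, 4), h)[1])
  expect_lt(abs(mean(draws2) - (2 + 6) / (1 + 2)), 4 * sd(draws2) / sqrt(4e4))
})
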