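#' Fit the PY-INAR(p) model by data-augmented Gibbs sampling
#'
#' Runs the marginal Gibbs sampler for the PY-INAR(p) model.  Each iteration
#' sweeps, in order: every latent maturation \eqn{m_{i,t}} from its exact
#' discrete conditional; the thinning vector \eqn{\alpha} coordinate-wise
#' from right-truncated Betas (so \eqn{\sum_i \alpha_i < 1} always holds);
#' every innovation rate \eqn{\lambda_t} from its Pitman-Yor urn
#' conditional; and finally a per-cluster refresh of the atom values, which
#' improves mixing by moving all rates in a cluster together.
#'
#' Initialization: \eqn{\alpha_i = 1/(2p)}, all maturations 0, all rates
#' equal to `mean(y)` (a single cluster).
#'
#' @param y a [count_series()] (or integer vector; `order` then applies).
#' @param hyper a [py_hyperparams()] object, e.g. from
#'   [elicit_hyperparams()].
#' @param order model order when `y` is a plain vector.
#' @param n_iter,n_burn,thin chain length, burn-in, and thinning interval;
#'   `(n_iter - n_burn)/thin` draws are retained.
#' @param dirichlet_a Dirichlet prior weights \eqn{a_1, \dots, a_p} for the
#'   thinning vector (the remainder weight \eqn{a_{p+1}} is fixed at 1,
#'   which is what gives the truncated-Beta conditionals).
#' @param seed optional integer seed (`set.seed` is called when supplied).
#' @param keep_lambda retain the full matrix of innovation-rate draws
#'   (needed for forecasting; the co-clustering tallies are accumulated
#'   regardless).
#' @param cocluster accumulate co-clustering pair counts across retained
#'   draws (needed for [coclustering_dissimilarity()]).
#' @param init optional list with components `alpha` and/or `lambda` used as
#'   the starting state (chains can thereby be warm-started).
#' @return An object of class `pyinar_fit` with components `draws` (list:
#'   `alpha` matrix, `k` integer vector, `lambda` matrix or `NULL`, `loglik`
#'   complete-data log-likelihood trace), `cocluster` (proportion of
#'   retained draws co-clustering each pair of epochs, or `NULL`), `y`,
#'   `hyper`, `model` (`"pyinar"` or `"inar"`), `config`, and `final_state`.
#' @examples
#' set.seed(7)
#' sim <- simulate_inar(0.15, mixture_innovations(), T = 120)
#' h <- elicit_hyperparams(k0 = 5, sigma = 0.5, lambda_max = 20,
#'                         n = length(sim$series) - 1)
#' fit <- fit_pyinar(sim$series, h, n_iter = 300, n_burn = 100)
#' fit
#' @export
fit_pyinar <- function(y, hyper, order = NULL,
                       n_iter = 6000L, n_burn = 1000L, thin = 1L,
                       dirichlet_a = NULL, seed = NULL,
                       keep_lambda = TRUE, cocluster = TRUE,
                       init = NULL) {
  run_gibbs(y, hyper, order, n_iter, n_burn, thin, dirichlet_a, seed,
            keep_lambda, cocluster, init, homogeneous = FALSE)
}

#' Fit the homogeneous INAR(p) baseline
#'
#' The homogeneous model constrains all innovation rates to one shared
#' \eqn{\lambda} with a \eqn{\mathrm{Gamma}(a_0, b_0)} prior; its full
#' conditional collapses to \eqn{\mathrm{Gamma}(a_0 + \sum_t (y_t - m_t),
#' b_0 + T - p)}.  The same Dirichlet prior is used for the thinning vector
#' as in [fit_pyinar()], so the two models differ only in the law of the
#' innovation rates.
#'
#' @inheritParams fit_pyinar
#' @param a0,b0 Gamma prior parameters for the shared rate (taken from
#'   `hyper` when one is supplied).
#' @return A `pyinar_fit` with `model = "inar"`.
#' @export
fit_inar <- function(y, a0 = 1, b0 = 1, hyper = NULL, order = NULL,
                     n_iter = 6000L, n_burn = 1000L, thin = 1L,
                     dirichlet_a = NULL, seed = NULL, keep_lambda = TRUE,
                     init = NULL) {
  if (is.null(hyper)) {
    # tau/sigma are inert in the homogeneous sampler; keep a valid object
    hyper <- py_hyperparams(tau = 1, sigma = 0, a0 = a0, b0 = b0)
  }
  run_gibbs(y, hyper, order, n_iter, n_burn, thin, dirichlet_a, seed,
            keep_lambda, cocluster = FALSE, init, homogeneous = TRUE)
}

run_gibbs <- function(y, hyper, order, n_iter, n_burn, thin, dirichlet_a,
                      seed, keep_lambda, cocluster, init, homogeneous) {
  stopifnot(inherits(hyper, "py_hyperparams"))
  y <- as_count_series(y, order = order)
  p <- series_order(y)
  if (is.null(dirichlet_a)) dirichlet_a <- rep(1, p)
  if (length(dirichlet_a) != p || any(dirichlet_a <= 0)) {
    stop("dirichlet_a must be p positive weights")
  }
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn)
  thin <- as.integer(thin)
  if (n_burn < 0 || n_iter <= n_burn || thin < 1L) {
    stop("need n_iter > n_burn >= 0 and thin >= 1")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  init_alpha <- if (!is.null(init$alpha)) as.numeric(init$alpha) else NULL
  init_lambda <- if (!is.null(init$lambda)) as.numeric(init$lambda) else NULL

  res <- .gibbs_pyinar(as.integer(y), p,
                       hyper$tau, hyper$sigma, hyper$a0, hyper$b0,
                       dirichlet_a, n_iter, n_burn, thin,
                       homogeneous, keep_lambda, cocluster,
                       init_alpha, init_lambda)
  n_keep <- res$n_keep
  draws <- list(
    alpha = res$alpha[seq_len(n_keep), , drop = FALSE],
    k = res$k[seq_len(n_keep)],
    lambda = if (keep_lambda) res$lambda[seq_len(n_keep), , drop = FALSE],
    loglik = res$loglik[seq_len(n_keep)])
  structure(list(
    draws = draws,
    cocluster = if (cocluster) res$cocount / n_keep,
    y = y, hyper = hyper,
    model = if (homogeneous) "inar" else "pyinar",
    config = list(n_iter = n_iter, n_burn = n_burn, thin = thin,
                  dirichlet_a = dirichlet_a, seed = seed),
    final_state = list(alpha = res$final_alpha, lambda = res$final_lambda,
                       m = res$final_m)),
    class = "pyinar_fit")
}

#' @export
print.pyinar_fit <- function(x, ...) {
  p <- series_order(x$y)
  cat(sprintf("%s(%d) fit: T = %d, %d retained draws\n",
              if (x$model == "inar") "INAR" else "PY-INAR",
              p, length(x$y), length(x$draws$k)))
  am <- colMeans(x$draws$alpha)
  cat("  posterior mean alpha:", paste(sprintf("%.4f", am), collapse = ", "),
      "\n")
  if (x$model == "pyinar") {
    cat(sprintf("  number of clusters K: posterior mean %.2f, mode %d\n",
                mean(x$draws$k), posterior_mode_k(x)))
  } else {
    cat(sprintf("  shared innovation rate: posterior mean %.3f\n",
                mean(x$draws$lambda[, 1])))
  }
  invisible(x)
}

#' Posterior summaries of the number of clusters
#'
#' `posterior_mode_k()` returns the most frequent value of `K` among the
#' retained draws (smallest value on ties); `posterior_mean_k()` returns
#' the posterior expectation \eqn{E[K \mid y]}.
#'
#' @param fit a `pyinar_fit`.
#' @return An integer (mode) or real (mean).
#' @export
posterior_mode_k <- function(fit) {
  tab <- table(fit$draws$k)
  as.integer(names(tab)[which.max(tab)])
}

#' @rdname posterior_mode_k
#' @export
posterior_mean_k <- function(fit) mean(fit$draws$k)

#' Write retained posterior draws to CSV
#'
#' Emits `draws.csv` (one row per retained iteration: the thinning
#' parameters, `k`, and the complete-data log-likelihood) and, when rate
#' draws were kept, `lambda.csv` (one row per retained iteration, one
#' column per epoch).
#'
#' @param fit a `pyinar_fit`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_draws <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- series_order(fit$y)
  df <- as.data.frame(fit$draws$alpha)
  names(df) <- paste0("alpha", seq_len(p))
  df$k <- fit$draws$k
  df$loglik <- fit$draws$loglik
  paths <- file.path(dir, "draws.csv")
  write.csv(df, paths, row.names = FALSE, quote = FALSE)
  if (!is.null(fit$draws$lambda)) {
    lp <- file.path(dir, "lambda.csv")
    lam <- as.data.frame(fit$draws$lambda)
    names(lam) <- paste0("t", p + seq_len(ncol(lam)))
    write.csv(lam, lp, row.names = FALSE, quote = FALSE)
    paths <- c(paths, lp)
  }
  invisible(paths)
}
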