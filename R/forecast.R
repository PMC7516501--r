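#' One-step-ahead posterior-predictive draws
#'
#' For each retained Gibbs draw, composes the one-step-ahead predictive of
#' \eqn{Y_{T+1}}: the next innovation rate \eqn{\lambda_{T+1}} follows the
#' Pitman-Yor predictive rule — fresh from \eqn{\mathrm{Gamma}(a_0, b_0)}
#' with probability proportional to \eqn{\tau + k\sigma}, or an existing
#' atom \eqn{\lambda^*_j} with probability proportional to
#' \eqn{\nu_j - \sigma} — and then
#' \eqn{Y_{T+1} = \sum_i \mathrm{Binomial}(y_{T+1-i}, \alpha_i) +
#' \mathrm{Poisson}(\lambda_{T+1})}.  For the homogeneous model the next
#' rate is the shared \eqn{\lambda} of the draw.
#'
#' @param fit a `pyinar_fit` with retained rate draws
#'   (`keep_lambda = TRUE`).
#' @param y optionally, the series to forecast from (defaults to the series
#'   the model was fitted to; its last `p` values feed the thinning terms).
#' @return An integer vector of predictive samples of \eqn{Y_{T+1}}, one
#'   per retained draw, of class `forecast_result` with attribute `horizon`
#'   (the epoch `T + 1` being predicted).
#' @export
predictive_draws <- function(fit, y = NULL) {
  stopifnot(inherits(fit, "pyinar_fit"))
  if (is.null(fit$draws$lambda)) {
    stop("forecasting needs retained rate draws (keep_lambda = TRUE)")
  }
  if (is.null(y)) y <- fit$y
  y <- as_count_series(y, order = series_order(fit$y))
  p <- series_order(y)
  T <- length(y)
  ytail <- as.integer(y)[T + 1 - seq_len(p)]  # y_T, y_{T-1}, ..., y_{T-p+1}
  lam <- fit$draws$lambda
  alpha <- fit$draws$alpha
  nd <- nrow(lam)
  n <- ncol(lam)
  h <- fit$hyper
  out <- integer(nd)
  for (r in seq_len(nd)) {
    if (fit$model == "inar") {
      lnew <- lam[r, 1]
    } else {
      atoms <- unique(lam[r, ])
      nu <- tabulate(match(lam[r, ], atoms))
      k <- length(atoms)
      w <- c(h$tau + k * h$sigma, nu - h$sigma)
      pick <- sample.int(k + 1L, 1L, prob = w / sum(w))
      lnew <- if (pick == 1L) rgamma(1, h$a0, rate = h$b0) else atoms[pick - 1L]
    }
    out[r] <- sum(rbinom(p, ytail, alpha[r, ])) + rpois(1, lnew)
  }
  structure(out, horizon = T + 1L, class = "forecast_result")
}

#' Point forecast from posterior-predictive samples
#'
#' The sample median, the functional that minimizes mean absolute error.
#' A median landing on a half-integer is rounded to the nearest integer,
#' ties toward even.  Posterior mean and mode are available for
#' sensitivity checks.
#'
#' @param samples non-negative integer predictive samples.
#' @param type `"median"` (default), `"mean"` or `"mode"`.
#' @return A non-negative number (integer for `"median"`/`"mode"`).
#' @examples
#' point_forecast(c(2, 2, 3))  # 2
#' @export
point_forecast <- function(samples, type = c("median", "mean", "mode")) {
  if (length(samples) == 0L) stop("no predictive samples")
  type <- match.arg(type)
  switch(type,
         median = round(median(as.numeric(samples))),
         mean = mean(as.numeric(samples)),
         mode = {
           tab <- table(samples)
           as.numeric(names(tab)[which.max(tab)])
         })
}

#' Rolling-origin cross-validated one-step-ahead forecasting
#'
#' For each origin among the last `n_test` epochs, the chosen model is
#' refitted on the data strictly before the origin (no future data leaks
#' into any fit), the one-step-ahead posterior predictive is sampled, and
#' the absolute error of the point forecast against the realized count is
#' recorded.  The report's MAE is the mean absolute error across origins.
#'
#' @param y a [count_series()].
#' @param model `"pyinar"` or `"inar"`.
#' @param n_test number of held-out origins at the end of the series.
#' @param hyper a [py_hyperparams()] for the fits; by default elicited per
#'   origin from `k0`, `sigma` and `lambda_max` on the training window.
#' @param k0,sigma,lambda_max elicitation settings used when `hyper` is
#'   `NULL` (`lambda_max` defaults to the training-window maximum).
#' @param n_iter,n_burn,thin chain settings per refit (shorter chains than
#'   a one-off fit are usually adequate).
#' @param order model order when `y` is a plain vector.
#' @param seed optional seed covering the whole cross-validation.
#' @return An object of class `cv_report`: a list with `origins`, `truth`,
#'   `forecast`, `abs_error`, `mae`, `model` and `order`.
#' @export
rolling_cv <- function(y, model = c("pyinar", "inar"), n_test = 10L,
                       hyper = NULL, k0 = 5, sigma = 0.5, lambda_max = NULL,
                       n_iter = 1500L, n_burn = 500L, thin = 1L,
                       order = NULL, seed = NULL) {
  model <- match.arg(model)
  y <- as_count_series(y, order = order)
  p <- series_order(y)
  T <- length(y)
  n_test <- as.integer(n_test)
  if (n_test < 1L) stop("n_test must be at least 1")
  min_train <- p + max(10L, 2L * p)
  if (T - n_test < min_train) {
    stop("insufficient training data before the first forecast origin")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  origins <- (T - n_test + 1L):T
  fc <- truth <- numeric(n_test)
  for (j in seq_along(origins)) {
    t0 <- origins[j]
    train <- count_series(as.integer(y)[seq_len(t0 - 1L)], order = p)
    h <- hyper
    if (is.null(h)) {
      lm <- if (is.null(lambda_max)) max(max(train), 1) else lambda_max
      k0j <- min(k0, length(train) - p - 1L)
      h <- if (model == "pyinar") {
        elicit_hyperparams(k0j, sigma, lm, n = length(train) - p)
      } else {
        base <- elicit_base_measure(lm)
        py_hyperparams(1, 0, base$a0, base$b0)
      }
    }
    fit <- if (model == "pyinar") {
      fit_pyinar(train, h, n_iter = n_iter, n_burn = n_burn, thin = thin,
                 cocluster = FALSE)
    } else {
      fit_inar(train, hyper = h, n_iter = n_iter, n_burn = n_burn,
               thin = thin)
    }
    fc[j] <- point_forecast(predictive_draws(fit))
    truth[j] <- as.integer(y)[t0]
  }
  structure(list(origins = origins, truth = truth, forecast = fc,
                 abs_error = abs(fc - truth), mae = mean(abs(fc - truth)),
                 model = model, order = p),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("rolling-origin CV: %s(%d), %d one-step-ahead origins\n",
              toupper(x$model), x$order, length(x$origins)))
  cat(sprintf("MAE = %.4f\n", x$mae))
  invisible(x)
}

#' Serialize a cross-validation report to CSV
#'
#' One row per origin (`origin`, `truth`, `forecast`, `abs_error`) plus a
#' trailing summary row carrying the MAE.
#'
#' @param report a `cv_report`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_cv_report <- function(report, path) {
  df <- data.frame(origin = c(report$origins, NA),
                   truth = c(report$truth, NA),
                   forecast = c(report$forecast, NA),
                   abs_error = c(report$abs_error, report$mae))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
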