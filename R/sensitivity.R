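#' Elbow sensitivity scan over the base-measure scale
#'
#' For each value of the reference scale `lambda_max` in a grid, elicits the
#' base measure by [elicit_base_measure()], solves the concentration
#' parameter from the prior expected cluster count `k0` ([solve_tau()]),
#' runs the Gibbs sampler, and records the posterior expected number of
#' clusters \eqn{E[K \mid y]}.  The scale at which the curve levels off —
#' its elbow — is a choice of `lambda_max` that avoids both extremes of the
#' base measure (mass piled near zero or spread so thin that fresh clusters
#' are never opened).
#'
#' The scan annotates the leveling-off point directly: the smallest grid
#' point whose \eqn{E[K \mid y]} is within 10% of the final plateau value
#' (the last grid point's).  When the curve shows no net decrease, or never
#' comes within that band before its last point, there is no distinct
#' elbow: the scan falls back to the chord-rule knee of [detect_elbow()]
#' and sets the `no_distinct_elbow` flag.
#'
#' A sampler failure at a grid point is caught: the point is flagged
#' (`NA` in the curve) and the scan continues.
#'
#' @param y a [count_series()].
#' @param k0 prior expected number of clusters.
#' @param sigma Pitman-Yor discount parameter.
#' @param grid increasing positive `lambda_max` values; default 10
#'   log-spaced points spanning `[max(y)/2, 20 max(y)]`, which covers the
#'   plausible innovation scales of the observed counts together with the
#'   diffuse-base-measure regime where the cluster count stabilizes.
#' @param n_iter,n_burn,thin chain settings per grid point (shorter chains
#'   than a final fit are usually adequate for locating the elbow).
#' @param seed optional seed for the whole scan.
#' @param order model order when `y` is a plain vector.
#' @return An object of class `elbow_curve`: a list with `lambda_max_grid`,
#'   `posterior_expected_k`, `chosen_lambda_max`, `elbow_index`,
#'   `no_distinct_elbow` flag, `k0`, `sigma`, and per-point `tau`, `a0`,
#'   `b0` and sampler diagnostics (`mean_loglik`, `failed`).
#' @export
elbow_scan <- function(y, k0, sigma, grid = NULL,
                       n_iter = 1500L, n_burn = 500L, thin = 1L,
                       seed = NULL, order = NULL) {
  y <- as_count_series(y, order = order)
  n <- length(y) - series_order(y)
  if (is.null(grid)) {
    grid <- exp(seq(log(max(max(y) / 2, 0.5)), log(20 * max(y)),
                    length.out = 10))
  }
  if (length(grid) < 4L) stop("lambda_max grid needs at least 4 points")
  if (any(grid <= 0)) stop("lambda_max grid must be positive")
  degenerate <- length(unique(grid)) == 1L
  if (!degenerate && any(diff(grid) <= 0)) {
    stop("lambda_max grid must be strictly increasing")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  tau <- solve_tau(k0, sigma, n)

  ek <- tau_v <- a0_v <- b0_v <- mll <- rep(NA_real_, length(grid))
  failed <- logical(length(grid))
  for (i in seq_along(grid)) {
    res <- tryCatch({
      base <- elicit_base_measure(grid[i])
      h <- py_hyperparams(tau, sigma, base$a0, base$b0)
      fit <- fit_pyinar(y, h, n_iter = n_iter, n_burn = n_burn, thin = thin,
                        keep_lambda = FALSE, cocluster = FALSE)
      list(ek = posterior_mean_k(fit), a0 = base$a0, b0 = base$b0,
           mll = mean(fit$draws$loglik))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed[i] <- TRUE
      warning(sprintf("grid point lambda_max = %.4g failed: %s",
                      grid[i], conditionMessage(res)))
    } else {
      ek[i] <- res$ek; a0_v[i] <- res$a0; b0_v[i] <- res$b0
      mll[i] <- res$mll; tau_v[i] <- tau
    }
  }

  ok <- !failed
  if (degenerate) {
    idx <- 1L; flag <- TRUE
  } else if (sum(ok) >= 4L) {
    gx <- grid[ok]; gy <- ek[ok]; m <- length(gy)
    plateau <- gy[m]
    level <- which(gy <= 1.1 * plateau)
    if (gy[m] < gy[1] && length(level) > 0L && level[1] < m) {
      idx <- which(ok)[level[1]]; flag <- FALSE
    } else {
      el <- detect_elbow(gx, gy)
      idx <- which(ok)[el$index]; flag <- TRUE
    }
  } else {
    idx <- which(ok)[1L]; flag <- TRUE
  }

  structure(list(lambda_max_grid = grid, posterior_expected_k = ek,
                 chosen_lambda_max = grid[idx], elbow_index = idx,
                 no_distinct_elbow = flag,
                 k0 = k0, sigma = sigma, tau = tau_v, a0 = a0_v, b0 = b0_v,
                 mean_loglik = mll, failed = failed),
            class = "elbow_curve")
}

#' Locate the elbow of a leveling-off curve
#'
#' Operationalizes the by-eye elbow: both axes are min-max normalized to
#' `[0, 1]` (so the choice is invariant to affine rescaling of either
#' axis), and the returned point maximizes the perpendicular distance to
#' the chord joining the first and last curve points, ties broken toward
#' smaller `x`.  A curve with no net decrease, or one that is essentially
#' straight, has no distinct elbow: the flag is set and (for the straight
#' case) the first interior point is returned.
#'
#' @param x strictly increasing abscissae (at least 4 points).
#' @param fx curve values at `x`.
#' @return A list with `x` (the elbow abscissa), `index`, and
#'   `no_distinct_elbow`.
#' @examples
#' detect_elbow(c(1, 2, 3, 4), c(10, 4, 3.5, 3.4))  # elbow at x = 2
#' @export
detect_elbow <- function(x, fx) {
  if (length(x) < 4L) stop("elbow detection needs at least 4 points")
  if (length(fx) != length(x)) stop("x and fx lengths differ")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  nx <- (x - min(x)) / (max(x) - min(x))
  rng <- max(fx) - min(fx)
  ny <- if (rng > 0) (fx - min(fx)) / rng else rep(0, length(fx))
  n <- length(x)
  # perpendicular distance to the chord through the first and last points
  dx <- nx[n] - nx[1]; dy <- ny[n] - ny[1]
  dist <- abs((nx - nx[1]) * dy - (ny - ny[1]) * dx) / sqrt(dx^2 + dy^2)
  flag <- FALSE
  if (max(dist) < 1e-2) {            # straight line
    return(list(x = x[2], index = 2L, no_distinct_elbow = TRUE))
  }
  if (fx[n] >= fx[1]) flag <- TRUE   # no net leveling-off from above
  idx <- which(dist == max(dist))[1L]
  list(x = x[idx], index = idx, no_distinct_elbow = flag)
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf("elbow scan: k0 = %g, sigma = %g, %d grid points\n",
              x$k0, x$sigma, length(x$lambda_max_grid)))
  df <- data.frame(lambda_max = x$lambda_max_grid,
                   E_K_posterior = x$posterior_expected_k)
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("chosen lambda_max = %.4g%s\n", x$chosen_lambda_max,
              if (x$no_distinct_elbow) " (no distinct elbow)" else ""))
  invisible(x)
}

#' Serialize an elbow curve to CSV
#'
#' One row per grid point with columns `lambda_max` and `E_K_posterior`,
#' for external plotting.
#'
#' @param curve an `elbow_curve`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_elbow_curve <- function(curve, path) {
  write.csv(data.frame(lambda_max = curve$lambda_max_grid,
                       E_K_posterior = curve$posterior_expected_k),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
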