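#' Full-conditional mixture weights for one innovation rate
#'
#' The Gibbs full conditional of \eqn{\lambda_t} is the mixture
#' \deqn{\lambda_t \mid \cdot \;\sim\; w_t \,
#'   \mathrm{Gamma}(y_t - m_t + a_0,\, b_0 + 1) +
#'   \sum_{r \ne t} \Big(1 - \frac{\sigma}{n_r}\Big)
#'   \lambda_r^{y_t - m_t} e^{-\lambda_r}\, \delta_{\{\lambda_r\}},}
#' with fresh-draw weight
#' \eqn{w_t = (\tau + k_{\setminus t}\sigma)\, b_0^{a_0}\,
#' \Gamma(y_t - m_t + a_0) / \{\Gamma(a_0)(b_0+1)^{y_t - m_t + a_0}\}},
#' where \eqn{n_r} counts the elements of \eqn{\lambda_{\setminus t}} equal
#' to \eqn{\lambda_r} and \eqn{k_{\setminus t}} is the number of distinct
#' values among them.  Grouping the per-observation terms by cluster uses
#' the identity \eqn{\sum_{r \in \mathrm{cluster}\ j} (1 - \sigma/n_r) =
#' n_j - \sigma}, giving per-atom weights
#' \eqn{(n_j - \sigma) (\lambda^*_j)^{y_t - m_t} e^{-\lambda^*_j}}.
#'
#' All weights are computed in log space and normalized.  The factorial
#' \eqn{1/(y_t - m_t)!} common to every component is omitted (it cancels on
#' normalization).
#'
#' @param residual the thinning residual \eqn{y_t - m_t \ge 0}.
#' @param atoms distinct innovation-rate values \eqn{\lambda^*_j} among
#'   \eqn{\lambda_{\setminus t}} (for `grouped = TRUE`), or the full vector
#'   \eqn{\lambda_{\setminus t}} (for `grouped = FALSE`).
#' @param sizes cluster sizes \eqn{n_j} matching `atoms` when
#'   `grouped = TRUE`; ignored otherwise (multiplicities are tabulated from
#'   `atoms`).
#' @param hyper a [py_hyperparams()] object.
#' @param grouped aggregate the existing-atom terms by cluster (the form the
#'   sampler uses) or keep one term per observation; the two
#'   parameterizations define the same transition kernel.
#' @return A list: `prob_new` (normalized fresh-draw probability),
#'   `prob_atoms` (normalized probabilities per atom or per observation) and
#'   `gamma_shape`, `gamma_rate` of the fresh-draw component.
#' @export
lambda_conditional_weights <- function(residual, atoms, sizes = NULL, hyper,
                                       grouped = TRUE) {
  stopifnot(inherits(hyper, "py_hyperparams"))
  if (residual < 0) stop("residual y_t - m_t must be non-negative")
  a0 <- hyper$a0; b0 <- hyper$b0; tau <- hyper$tau; sigma <- hyper$sigma
  if (grouped) {
    if (is.null(sizes) || length(sizes) != length(atoms)) {
      stop("grouped form needs one size per atom")
    }
    k <- length(atoms)
    lw_atom <- log(sizes - sigma) + residual * log(atoms) - atoms
  } else {
    tab <- table(match(atoms, unique(atoms)))
    n_r <- as.numeric(tab)[match(atoms, unique(atoms))]
    k <- length(unique(atoms))
    lw_atom <- log1p(-sigma / n_r) + residual * log(atoms) - atoms
  }
  if (length(atoms) == 0L) {
    k <- 0L
    lw_atom <- numeric(0)
  }
  lw_new <- log(tau + k * sigma) + a0 * log(b0) +
    lgamma(residual + a0) - lgamma(a0) - (residual + a0) * log(b0 + 1)
  lw <- c(lw_new, lw_atom)
  mx <- max(lw)
  if (!is.finite(mx)) stop("all lambda full-conditional weights underflowed")
  w <- exp(lw - mx)
  w <- w / sum(w)
  list(prob_new = w[1], prob_atoms = w[-1],
       gamma_shape = residual + a0, gamma_rate = b0 + 1)
}

#' Draw one innovation rate from its full conditional
#'
#' Samples \eqn{\lambda_t} from the mixture described in
#' [lambda_conditional_weights()]: with the fresh-draw probability a new
#' atom from \eqn{\mathrm{Gamma}(y_t - m_t + a_0, b_0 + 1)}, otherwise one
#' of the existing atoms.
#'
#' @inheritParams lambda_conditional_weights
#' @return A positive scalar (either a fresh Gamma draw or an existing
#'   atom).
#' @export
sample_lambda_t <- function(residual, atoms, sizes, hyper) {
  w <- lambda_conditional_weights(residual, atoms, sizes, hyper,
                                  grouped = TRUE)
  if (runif(1) < w$prob_new || length(atoms) == 0L) {
    rgamma(1, shape = w$gamma_shape, rate = w$gamma_rate)
  } else {
    atoms[sample.int(length(atoms), 1L,
                     prob = w$prob_atoms / sum(w$prob_atoms))]
  }
}

#' Draw from a right-truncated Beta distribution
#'
#' Inverse-CDF sampling of a Beta(`shape1`, `shape2`) restricted to
#' `(0, bound)`, via the regularized incomplete beta function and its
#' inverse; if the truncated mass falls below `1e-12` (where the inverse
#' CDF loses accuracy) the draw falls back to rejection sampling.
#'
#' @param n number of draws.
#' @param shape1,shape2 Beta parameters.
#' @param bound right truncation point in `(0, 1]`.
#' @return `n` draws in `(0, bound)`.
#' @export
rtbeta <- function(n, shape1, shape2, bound = 1) {
  if (bound <= 0 || bound > 1) stop("truncation bound must lie in (0, 1]")
  mass <- pbeta(bound, shape1, shape2)
  if (mass >= 1e-12) {
    return(qbeta(runif(n) * mass, shape1, shape2))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- rbeta(1, shape1, shape2)
      if (x < bound) { out[i] <- x; break }
    }
  }
  out
}

#' Draw the thinning vector from its full conditional
#'
#' With the Dirichlet prior on \eqn{(\alpha_1, \dots, \alpha_p;
#' \alpha_{p+1})} and \eqn{a_{p+1} = 1}, each \eqn{\alpha_i} has a
#' right-truncated Beta full conditional
#' \deqn{\alpha_i \mid \cdot \sim \mathrm{TBeta}\Big(a_i + \sum_t m_{i,t},\;
#'   1 + \sum_t (y_{t-i} - m_{i,t}),\; 1 - \sum_{j \ne i}\alpha_j\Big),}
#' so the updated vector always stays in the non-explosive region
#' \eqn{\sum_i \alpha_i < 1}.  For `p = 1` the truncation bound is 1 and the
#' draw is an ordinary Beta.
#'
#' @param alpha current thinning vector (length `p`).
#' @param m maturation matrix (`p` rows, `T - p` columns).
#' @param y a [count_series()].
#' @param dirichlet_a Dirichlet hyperparameters \eqn{a_1, \dots, a_p}
#'   (\eqn{a_{p+1} = 1} is fixed).
#' @return The updated thinning vector.
#' @export
sample_alpha <- function(alpha, m, y, dirichlet_a = rep(1, length(alpha))) {
  y <- as_count_series(y)
  p <- series_order(y)
  stopifnot(length(alpha) == p, nrow(m) == p)
  yv <- as.integer(y)
  n <- length(y) - p
  for (i in seq_len(p)) {
    lag_counts <- yv[(p + 1:n) - i]
    s1 <- dirichlet_a[i] + sum(m[i, ])
    s2 <- 1 + sum(lag_counts - m[i, ])
    bound <- 1 - sum(alpha[-i])
    if (bound <= 0) stop("thinning vector left the non-explosive region")
    alpha[i] <- rtbeta(1, s1, s2, bound)
  }
  alpha
}

#' Exact full conditional of one latent maturation
#'
#' The single-site conditional of \eqn{m_{i,t}} is, up to normalization,
#' \deqn{p(m_{i,t} \mid \cdot) \propto
#'   \frac{1}{m_{i,t}!\,(y_t - \sum_j m_{j,t})!\,(y_{t-i} - m_{i,t})!}
#'   \left(\frac{\alpha_i}{\lambda_t (1 - \alpha_i)}\right)^{m_{i,t}}}
#' on the support \eqn{\{0, \dots, \min(y_t - \sum_{j \ne i} m_{j,t},\,
#' y_{t-i})\}}.  `maturation_pmf()` returns the normalized enumeration;
#' `sample_maturation()` draws from it (a categorical draw: the support is
#' small because counts are small).
#'
#' @param yt observed count at epoch `t`.
#' @param ylag observed count at epoch `t - i`.
#' @param rest sum of the other maturations \eqn{\sum_{j \ne i} m_{j,t}}.
#' @param alpha_i thinning probability of lag `i`.
#' @param lambda_t innovation rate at epoch `t`.
#' @return `maturation_pmf()`: probabilities over support `0..hi`;
#'   `sample_maturation()`: one integer draw.
#' @export
maturation_pmf <- function(yt, ylag, rest, alpha_i, lambda_t) {
  hi <- min(yt - rest, ylag)
  if (hi < 0) stop("inconsistent maturations: support is empty")
  mseq <- 0:hi
  if (alpha_i <= 0) return(as.numeric(mseq == 0))
  if (alpha_i >= 1) return(as.numeric(mseq == hi))
  lw <- mseq * (log(alpha_i) - log(lambda_t) - log1p(-alpha_i)) -
    lgamma(mseq + 1) - lgamma(yt - rest - mseq + 1) - lgamma(ylag - mseq + 1)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' @rdname maturation_pmf
#' @export
sample_maturation <- function(yt, ylag, rest, alpha_i, lambda_t) {
  pr <- maturation_pmf(yt, ylag, rest, alpha_i, lambda_t)
  sample.int(length(pr), 1L, prob = pr) - 1L
}

#' Refresh the innovation-rate atoms cluster by cluster
#'
#' At the end of each Gibbs iteration, mixing is improved by resampling all
#' rates inside each cluster simultaneously:
#' \deqn{\lambda^*_j \mid \cdot \sim \mathrm{Gamma}\Big(a_0 +
#'   \sum_{t \in \mathrm{cluster}\ j} (y_t - m_t),\; b_0 + \nu_j\Big),}
#' where \eqn{\nu_j} is the cluster size.  Memberships are unchanged; only
#' the shared atom values move.
#'
#' @param lambda current innovation-rate vector (epochs `p+1..T`).
#' @param residuals the thinning residuals \eqn{y_t - m_t} per epoch.
#' @param hyper a [py_hyperparams()] object.
#' @return The refreshed `lambda` vector (same clustering, new atom values).
#' @export
refresh_cluster_values <- function(lambda, residuals, hyper) {
  stopifnot(inherits(hyper, "py_hyperparams"),
            length(lambda) == length(residuals))
  z <- match(lambda, unique(lambda))
  for (j in seq_along(unique(lambda))) {
    idx <- which(z == j)
    newval <- rgamma(1, shape = hyper$a0 + sum(residuals[idx]),
                     rate = hyper$b0 + length(idx))
    lambda[idx] <- newval
  }
  lambda
}
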