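#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Data-augmented marginal Gibbs sampler for the PY-INAR(p) model.
//
// State: thinning vector alpha[0..p-1], innovation rates lambda[0..n-1]
// (n = T - p, site s corresponds to epoch t = p + 1 + s in 1-based time),
// maturation matrix m[i][s] with 0 <= m[i][s] <= y[t-i] and
// sum_i m[i][s] <= y[t].  Cluster bookkeeping: z[s] = cluster of site s,
// atom values lamstar[j], occupancies nu[j], count k.
//
// Sweep order per iteration: all maturations (systematic site scan), the
// thinning vector (right-truncated Beta coordinates), all lambda sites
// (Pitman-Yor urn conditional), then the Escobar-West style per-cluster
// refresh of the atom values.

static double rtbeta1(double s1, double s2, double bound) {
  if (bound >= 1.0) return R::rbeta(s1, s2);
  double mass = R::pbeta(bound, s1, s2, 1, 0);
  if (mass >= 1e-12) {
    double u = R::runif(0.0, 1.0) * mass;
    double x = R::qbeta(u, s1, s2, 1, 0);
    if (x >= bound) x = bound * (1.0 - 1e-12);
    return x;
  }
  for (int tries = 0; tries < 100000; ++tries) {
    double x = R::rbeta(s1, s2);
    if (x < bound) return x;
  }
  // essentially zero truncated mass: pin just inside the bound
  return bound * (1.0 - 1e-9);
}

// [[Rcpp::export(name = ".gibbs_pyinar")]]
List gibbs_pyinar(IntegerVector y, int p,
                  double tau, double sigma, double a0, double b0,
                  NumericVector dirichlet_a,
                  int n_iter, int n_burn, int thin,
                  bool homogeneous,
                  bool keep_lambda, bool cocluster,
                  Nullable<NumericVector> init_alpha = R_NilValue,
                  Nullable<NumericVector> init_lambda = R_NilValue) {
  const int T = y.size();
  const int n = T - p;
  if (n < 1) stop("series length must exceed the order");
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter");

  // log-factorial lookup for the maturation conditional
  int ymax = 0;
  for (int t = 0; t < T; ++t) { if (y[t] < 0) stop("negative count"); if (y[t] > ymax) ymax = y[t]; }
  std::vector<double> lfact(ymax + 2);
  for (int v = 0; v <= ymax + 1; ++v) lfact[v] = R::lgammafn(v + 1.0);

  std::vector<double> alpha(p, 1.0 / (2.0 * p));
  std::vector<double> lambda(n);
  std::vector<std::vector<int> > m(p, std::vector<int>(n, 0));

  double ybar = 0.0; for (int t = 0; t < T; ++t) ybar += y[t];
  ybar /= T; if (ybar <= 0.0) ybar = 0.5;
  for (int s = 0; s < n; ++s) lambda[s] = ybar;  // one shared cluster

  if (init_alpha.isNotNull()) {
    NumericVector ia(init_alpha);
    if (ia.size() != p) stop("init_alpha must have length p");
    for (int i = 0; i < p; ++i) alpha[i] = ia[i];
  }
  if (init_lambda.isNotNull()) {
    NumericVector il(init_lambda);
    if (il.size() != n) stop("init_lambda must have length T - p");
    for (int s = 0; s < n; ++s) lambda[s] = il[s];
  }

  // cluster bookkeeping from lambda
  std::vector<int> z(n);
  std::vector<double> lamstar;
  std::vector<int> nu;
  for (int s = 0; s < n; ++s) {
    int j = -1;
    for (size_t q = 0; q < lamstar.size(); ++q)
      if (lamstar[q] == lambda[s]) { j = (int)q; break; }
    if (j < 0) { lamstar.push_back(lambda[s]); nu.push_back(0); j = (int)lamstar.size() - 1; }
    z[s] = j; nu[j]++;
  }

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  NumericMatrix alpha_draws(n_keep, p);
  IntegerVector k_draws(n_keep);
  NumericMatrix lambda_draws(keep_lambda ? n_keep : 0, keep_lambda ? n : 0);
  NumericVector loglik_draws(n_keep);
  NumericMatrix cocount(cocluster ? n : 0, cocluster ? n : 0);

  std::vector<double> lw(64);
  std::vector<int> msum(n, 0);
  RNGScope scope;
  int kept = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- maturations: systematic scan i = 1..p, sites s = 0..n-1
    for (int s = 0; s < n; ++s) {
      int t = p + s;                 // 0-based index of epoch t = p+1+s
      for (int i = 1; i <= p; ++i) {
        int rest = 0;
        for (int j = 0; j < p; ++j) if (j != i - 1) rest += m[j][s];
        int ylag = y[t - i];
        int hi = std::min(y[t] - rest, ylag);
        int draw = 0;
        if (hi > 0) {
          double ai = alpha[i - 1];
          if (ai <= 0.0) draw = 0;
          else if (ai >= 1.0) draw = hi;
          else {
            double lr = std::log(ai) - std::log(lambda[s]) - std::log1p(-ai);
            if ((int)lw.size() < hi + 1) lw.resize(hi + 1);
            double mx = -INFINITY;
            for (int mm = 0; mm <= hi; ++mm) {
              double v = mm * lr - lfact[mm] - lfact[y[t] - rest - mm] - lfact[ylag - mm];
              lw[mm] = v; if (v > mx) mx = v;
            }
            double tot = 0.0;
            for (int mm = 0; mm <= hi; ++mm) { lw[mm] = std::exp(lw[mm] - mx); tot += lw[mm]; }
            double u = R::runif(0.0, 1.0) * tot, c = 0.0;
            draw = hi;
            for (int mm = 0; mm <= hi; ++mm) { c += lw[mm]; if (u <= c) { draw = mm; break; } }
          }
        }
        m[i - 1][s] = draw;
      }
    }
    for (int s = 0; s < n; ++s) {
      int tot = 0; for (int i = 0; i < p; ++i) tot += m[i][s];
      msum[s] = tot;
    }

    // --- thinning vector: truncated-Beta coordinates
    for (int i = 1; i <= p; ++i) {
      double s1 = dirichlet_a[i - 1], s2 = 1.0;
      for (int s = 0; s < n; ++s) {
        int t = p + s;
        s1 += m[i - 1][s];
        s2 += y[t - i] - m[i - 1][s];
      }
      double bound = 1.0;
      for (int j = 0; j < p; ++j) if (j != i - 1) bound -= alpha[j];
      if (bound <= 0.0) stop("thinning vector left the non-explosive region");
      alpha[i - 1] = rtbeta1(s1, s2, bound);
    }

    // --- innovation rates
    if (homogeneous) {
      double shape = a0, rate = b0 + n;
      for (int s = 0; s < n; ++s) shape += y[p + s] - msum[s];
      double lam = R::rgamma(shape, 1.0 / rate);
      for (int s = 0; s < n; ++s) { lambda[s] = lam; z[s] = 0; }
      lamstar.assign(1, lam); nu.assign(1, n);
    } else {
      const double lg_a0 = R::lgammafn(a0);
      for (int s = 0; s < n; ++s) {
        // remove site s from its cluster
        int j = z[s];
        nu[j]--;
        if (nu[j] == 0) {
          int last = (int)lamstar.size() - 1;
          if (j != last) {
            lamstar[j] = lamstar[last]; nu[j] = nu[last];
            for (int q = 0; q < n; ++q) if (z[q] == last) z[q] = j;
          }
          lamstar.pop_back(); nu.pop_back();
        }
        int k = (int)lamstar.size();
        int d = y[p + s] - msum[s];
        if ((int)lw.size() < k + 1) lw.resize(k + 1);
        double lw_new = std::log(tau + k * sigma) + a0 * std::log(b0) +
          R::lgammafn(d + a0) - lg_a0 - (d + a0) * std::log(b0 + 1.0);
        double mx = lw_new;
        lw[0] = lw_new;
        for (int q = 0; q < k; ++q) {
          double v = std::log(nu[q] - sigma) + d * std::log(lamstar[q]) - lamstar[q];
          lw[q + 1] = v; if (v > mx) mx = v;
        }
        if (!std::isfinite(mx)) stop("lambda full-conditional weights underflowed");
        double tot = 0.0;
        for (int q = 0; q <= k; ++q) { lw[q] = std::exp(lw[q] - mx); tot += lw[q]; }
        double u = R::runif(0.0, 1.0) * tot, c = 0.0;
        int pick = k;
        for (int q = 0; q <= k; ++q) { c += lw[q]; if (u <= c) { pick = q; break; } }
        if (pick == 0) {
          double lam = R::rgamma(d + a0, 1.0 / (b0 + 1.0));
          lamstar.push_back(lam); nu.push_back(1);
          z[s] = (int)lamstar.size() - 1;
          lambda[s] = lam;
        } else {
          z[s] = pick - 1;
          nu[pick - 1]++;
          lambda[s] = lamstar[pick - 1];
        }
      }

      // --- per-cluster refresh of the atom values
      int k = (int)lamstar.size();
      std::vector<double> shape(k, a0);
      for (int s = 0; s < n; ++s) shape[z[s]] += y[p + s] - msum[s];
      for (int j = 0; j < k; ++j) {
        lamstar[j] = R::rgamma(shape[j], 1.0 / (b0 + nu[j]));
      }
      for (int s = 0; s < n; ++s) lambda[s] = lamstar[z[s]];
    }

    // --- record
    if (iter > n_burn && ((iter - n_burn - 1) % thin == 0)) {
      for (int i = 0; i < p; ++i) alpha_draws(kept, i) = alpha[i];
      k_draws[kept] = (int)lamstar.size();
      if (keep_lambda)
        for (int s = 0; s < n; ++s) lambda_draws(kept, s) = lambda[s];
      // complete-data log-likelihood log p(y, m | alpha, lambda)
      double ll = 0.0;
      for (int s = 0; s < n; ++s) {
        int t = p + s;
        for (int i = 1; i <= p; ++i)
          ll += R::dbinom(m[i - 1][s], y[t - i], alpha[i - 1], 1);
        ll += R::dpois(y[t] - msum[s], lambda[s], 1);
      }
      loglik_draws[kept] = ll;
      if (cocluster) {
        int k = (int)lamstar.size();
        std::vector<std::vector<int> > members(k);
        for (int s = 0; s < n; ++s) members[z[s]].push_back(s);
        for (int j = 0; j < k; ++j) {
          const std::vector<int>& mem = members[j];
          for (size_t a = 0; a < mem.size(); ++a)
            for (size_t b = a; b < mem.size(); ++b) {
              cocount(mem[a], mem[b]) += 1.0;
              if (b != a) cocount(mem[b], mem[a]) += 1.0;
            }
        }
      }
      kept++;
    }
  }

  IntegerMatrix m_out(p, n);
  for (int i = 0; i < p; ++i)
    for (int s = 0; s < n; ++s) m_out(i, s) = m[i][s];

  return List::create(
    _["alpha"] = alpha_draws,
    _["k"] = k_draws,
    _["lambda"] = lambda_draws,
    _["loglik"] = loglik_draws,
    _["cocount"] = cocount,
    _["n_keep"] = kept,
    _["final_alpha"] = NumericVector(alpha.begin(), alpha.end()),
    _["final_lambda"] = NumericVector(lambda.begin(), lambda.end()),
    _["final_m"] = m_out);
}

// Sequential-urn sampler for the number of Pitman-Yor clusters: an
// independent Monte-Carlo oracle for num_clusters_pmf() and
// expected_num_clusters().
// [[Rcpp::export(name = ".urn_num_clusters")]]
IntegerVector urn_num_clusters(int n, double tau, double sigma, int reps) {
  IntegerVector out(reps);
  RNGScope scope;
  std::vector<double> sizes;
  for (int r = 0; r < reps; ++r) {
    sizes.clear();
    sizes.push_back(1.0);
    for (int i = 1; i < n; ++i) {
      double k = (double)sizes.size();
      double tot = tau + i;
      double u = R::runif(0.0, 1.0) * tot;
      double c = tau + k * sigma;
      if (u <= c) { sizes.push_back(1.0); continue; }
      bool placed = false;
      for (size_t j = 0; j < sizes.size(); ++j) {
        c += sizes[j] - sigma;
        if (u <= c) { sizes[j] += 1.0; placed = true; break; }
      }
      if (!placed) sizes.back() += 1.0;
    }
    out[r] = (int)sizes.size();
  }
  return out;
}
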