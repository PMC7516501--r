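---
title: "Modelling count time series with Pitman-Yor clustered innovation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling count time series with Pitman-Yor clustered innovation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyinar)
```

## The model

An integer-valued autoregression of order $p$ relates the count at epoch
$t$ to the preceding $p$ counts through binomial thinning,

$$Y_t = \alpha_1 \circ Y_{t-1} + \cdots + \alpha_p \circ Y_{t-p} + Z_t,
\qquad t \ge p + 1,$$

where $\alpha_i \circ Y_{t-i}$ is a $\mathrm{Binomial}(Y_{t-i}, \alpha_i)$
number of "survivors" of the count $p$ epochs back, and the innovation
$Z_t \sim \mathrm{Poisson}(\lambda_t)$ counts new arrivals.  In the
classical INAR($p$) model all innovation rates are one constant
$\lambda$.  Real count series — disease cases, event counts, earthquakes —
often move through regimes of different innovation intensity, so this
package lets the rates vary with $t$ and places a Pitman-Yor process at
the top of the hierarchy:

$$\lambda_{p+1}, \dots, \lambda_T \mid G \overset{iid}{\sim} G,
\qquad G \sim PY(\tau, \sigma, G_0),
\qquad G_0 = \mathrm{Gamma}(a_0, b_0).$$

Realizations of a Pitman-Yor process are discrete with probability one, so
the rates are exchangeable but *tied*: the model clusters epochs by their
innovation intensity, with the number of clusters $K$ inferred rather than
fixed.  The discount $\sigma \in [0, 1)$ and concentration $\tau > -\sigma$
control the clustering: $\sigma = 0$ recovers the Dirichlet process, and
larger $\sigma$ gives heavier-tailed cluster-size distributions and, as
shown below, markedly more robust posterior inference on $K$.

The thinning vector gets a Dirichlet prior on
$(\alpha_1, \dots, \alpha_p; 1 - \sum_i \alpha_i)$, which places *all* of
its mass on the non-explosive region $\sum_i \alpha_i < 1$.  This matters:
with independent uniform priors on the $\alpha_i$ the non-explosive region
only receives mass $1/p!$.  Fixing the last Dirichlet weight $a_{p+1} = 1$
makes every $\alpha_i$ conditional a right-truncated Beta, sampled here by
inverse CDF.

## The Gibbs sampler

Conditioning on latent *maturations* $M_{i,t} \sim
\mathrm{Binomial}(y_{t-i}, \alpha_i)$ — the number of epoch-$(t-i)$
survivors present at $t$ — makes every full conditional tractable; summing
the augmented joint over the maturations returns the exact likelihood, a
fact the test suite verifies by brute-force enumeration on small series.
Each iteration sweeps:

1. every $m_{i,t}$ from its exact discrete conditional (systematic scan;
   the support is $\{0, \dots, \min(y_t - \sum_{j\ne i} m_{j,t},
   y_{t-i})\}$, small because counts are small);
2. every $\alpha_i$ from its truncated Beta;
3. every $\lambda_t$ from its marginal urn conditional: a fresh
   $\mathrm{Gamma}(y_t - m_t + a_0, b_0 + 1)$ atom with weight
   proportional to $(\tau + k_{\setminus t}\sigma)\, b_0^{a_0}
   \Gamma(y_t - m_t + a_0) / \{\Gamma(a_0) (b_0 + 1)^{y_t - m_t + a_0}\}$,
   or an existing atom $\lambda^*_j$ with weight
   $(n_j - \sigma) (\lambda^*_j)^{y_t - m_t} e^{-\lambda^*_j}$
   (all weights in log space; the common $1/(y_t - m_t)!$ cancels);
4. a per-cluster refresh $\lambda^*_j \sim \mathrm{Gamma}(a_0 +
   \sum_{t \in j} (y_t - m_t), b_0 + \nu_j)$, which moves all members of a
   cluster together and is what makes the chain mix across cluster
   configurations.

The sweep is implemented in compiled code (`src/gibbs.cpp`) with incremental
cluster bookkeeping, and driven by R's RNG so `set.seed()` controls every
draw.  The same single-site conditionals are exposed as pure R functions
(`lambda_conditional_weights()`, `sample_maturation()`, `rtbeta()`, ...)
whose exact enumerations serve as distributional oracles in the tests; the
compiled kernel itself is validated by a Geweke-style
successive-conditional test (alternating data simulation and posterior
sweeps preserves the prior of $\alpha$ on a tiny model) and by parameter
recovery on simulated data.

Initialization is deliberately simple and valid: $\alpha_i = 1/(2p)$, all
maturations zero, all rates equal to $\bar y$ (one cluster).  Default chain
lengths are 6000 iterations with 1000 burn-in; on a modern single core a
$T = 1000$ fit takes well under a minute.

## Prior elicitation and the elbow

Two devices reduce the hyperparameter space to interpretable knobs.

*Concentration from a cluster budget.*  The prior expectation of $K$ among
$n = T - p$ Pitman-Yor draws has closed forms — $\tau\{\psi(\tau + n) -
\psi(\tau)\}$ for $\sigma = 0$, and $(\tau + \sigma)_n / \{\sigma
(\tau + 1)_{n-1}\} - \tau/\sigma$ for $\sigma > 0$, with rising factorials
computed through `lgamma` — and is strictly increasing in $\tau$, so
`solve_tau()` finds by bisection the $\tau$ matching a user-chosen prior
expected cluster count $k_0$.  The full prior law of $K$
(`num_clusters_pmf()`) uses generalized factorial coefficients computed by
their triangular recurrence in log space; for $0 \le \sigma < 1$ every term
of the recurrence is non-negative, and both the recurrence and its
$\sigma = 0$ Stirling-number limit are validated against a sequential-urn
Monte Carlo oracle.

*Base measure from a single scale.*  Instead of choosing $(a_0, b_0)$
directly, choose one scale $\lambda_{\max}$ and take the Gamma closest (in
Kullback-Leibler divergence from a $\mathrm{Uniform}[0, \lambda_{\max}]$
reference) to that uniform.  The divergence has a closed form whose
stationarity in $b_0$ gives $b_0 = 2 a_0 / \lambda_{\max}$; substituting
this profile reduces the minimization to one dimension in $a_0$, whose
solution ($a_0 \approx 1.78$) does not depend on $\lambda_{\max}$ at all.
This also removes the flat valley that stalls naive two-dimensional
optimizers.  The support of $G_0$ is not truncated; the uniform is only a
reference.

*The elbow.*  Both extremes of the base measure suppress the fresh-atom
weight in the $\lambda_t$ conditional, so the posterior expected number of
clusters $E[K \mid y]$ traced over a $\lambda_{\max}$ grid first falls
steeply and then levels off.  `elbow_scan()` runs the sampler per grid
point and annotates the leveling-off point.  Two operational choices were
made here, both genuinely open:

* **Grid.**  Ten log-spaced points on $[\max(y)/2,\, 20\max(y)]$.  The
  lower end keeps the descending limb visible without entering the
  degenerate concentrated-base-measure regime; the upper end extends far
  enough that $E[K \mid y]$ has actually stabilized — on the benchmark
  simulation the curve is still falling at $5\max(y)$, so a narrower grid
  would terminate mid-descent.
* **Selection rule.**  The scan picks the *smallest grid point whose*
  $E[K \mid y]$ *is within 10% of the final plateau value* (the last grid
  point's).  A maximum-distance-to-chord knee rule is also provided
  (`detect_elbow()`, with min-max normalization of both axes so the choice
  is scale-free) and is used as a fallback when the curve never levels;
  applied directly to these curves, however, the chord knee lands in the
  middle of the descent — far from where the values level off, which is
  what the elbow criterion is after — so the plateau rule is the default.

## Posterior clustering point estimate

From the retained draws the package tallies co-clustering probabilities
and forms the dissimilarity $d_{rt} = \Pr\{\lambda_r \ne \lambda_t \mid
y\}$ (exact floating-point equality is correct within a draw because
cluster members share one atom by construction).  $D$ is generally not a
metric, but classical (Torgerson) multidimensional scaling — double-center
$-d^2/2$, keep the top two eigenpairs, clip negative eigenvalues — still
yields a useful planar embedding, and is deterministic, unlike iterative
stress majorization.  Ward-linkage hierarchical clustering of the embedding
is cut at a chosen number of clusters (default: the posterior mode of
$K$).  When ground-truth component labels exist, predicted labels are
matched to them by the trace-maximizing permutation (exhaustive, up to six
labels) before computing the confusion matrix and accuracy.

## Forecasting

The one-step-ahead posterior predictive composes, per retained draw, the
Pitman-Yor predictive rule for the next rate — fresh from
$\mathrm{Gamma}(a_0, b_0)$ with probability $(\tau + k\sigma)/(\tau + n)$,
else an existing atom with probability $\propto \nu_j - \sigma$ — with the
INAR functional relation.  The point forecast is the predictive median
(the MAE-optimal functional; half-integer medians round to even), with
mean and mode available for sensitivity.  `rolling_cv()` refits the model
from scratch at every origin on the data strictly before it, so no future
information leaks into any forecast.  The homogeneous INAR($p$) baseline
uses the same Dirichlet thinning prior and a single conjugate
$\mathrm{Gamma}$ rate, so the comparison isolates the effect of rate
heterogeneity.

## What the simulations do and do not show

The built-in generator reproduces the benchmark design used throughout:
a first-order model with thinning parameter $0.15$ and $T = 1000$, with
innovations from an equal-weight mixture of Poisson(1), Poisson(8) and
Poisson(15), and the latent mixture component of every epoch recorded so
cluster recovery can be scored.  Under that design the full pipeline
assigns roughly 83% of epochs to the correct component, and with
$\sigma = 0.75$ the posterior mode of $K$ equals 3 — the true number of
components — for every prior budget $k_0 \in \{4, 10, 16, 30\}$, which is
the robustness property that motivates preferring a Pitman-Yor over a
Dirichlet process here.

The generator draws each epoch's mixture component independently; it does
not emulate regime *persistence* (Markov switching), covariate effects,
overdispersion within a regime, or non-Poisson innovations, so passing
these checks says nothing about such features in real data.  The
forecasting comparison uses series whose rates mix a common and a rare
burst regime; with regimes of comparable frequency the exchangeable
predictive averages over clusters and the advantage over the homogeneous
model can vanish.

Problem sizes used by the test suite and the acceptance script: three
replicate $T = 1000$ pipeline runs at default chain lengths for the
accuracy check; scan chains of 800–1500 iterations per grid point; $10^5$
urn replicates and $10^6$ uniform draws for the Monte-Carlo identities;
forecasting comparisons on $T = 140$ series with six origins and six
replicates.

## Numerical and degenerate-input choices

* All mixture weights (urn, maturation, rate conditionals) are computed in
  log space with a max shift; an all-`-Inf` weight vector raises rather
  than silently renormalizing.
* `loglik_direct()` is an enumeration oracle, exponential in $p$ by
  construction; it refuses $p > 3$ or counts above 30.
* Truncated-Beta sampling inverts the regularized incomplete beta; when
  the truncated mass falls below $10^{-12}$ it falls back to rejection.
* A degenerate all-equal elbow grid returns its first point, flagged; a
  failed sampler run at a grid point flags that point and the scan
  continues.
* An all-zero dissimilarity matrix embeds every epoch at the origin;
  `cut_clusters()` with one cluster or with as many clusters as points
  short-circuits to the trivial labelings.
* Ties in the chord rule break toward smaller $\lambda_{\max}$; ties in
  the posterior mode of $K$ break toward fewer clusters.

## Known limitations

The sampler uses single-site urn updates plus the cluster refresh; no
split-merge moves are implemented, so mixing over $K$ can be slow for very
long series with subtle rate differences.  The discount and concentration
parameters are fixed by elicitation, not sampled.  Negative-discount
Pitman-Yor processes are out of scope.  Forecasting is one-step-ahead
only.
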