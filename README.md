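# pyinar

Semi-parametric Bayesian modelling of count time series: the **PY-INAR(p)**
model, an integer-valued autoregression whose Poisson innovation rates are
clustered by a Pitman-Yor process.

## The problem and the model

Count series — yearly numbers of strong earthquakes, weekly disease cases,
daily event counts — are often modelled by the INAR(p) autoregression

```
Y_t = alpha_1 ∘ Y_{t-1} + ... + alpha_p ∘ Y_{t-p} + Z_t,
```

where `alpha ∘ Y` is binomial thinning (each of the `Y` previous cases
survives independently with probability `alpha`) and the innovation
`Z_t ~ Poisson(lambda_t)` counts new arrivals.  The classical model forces
one constant rate `lambda`; real series move through regimes of different
intensity.  Here the rates are exchangeable draws from a random discrete
distribution,

```
lambda_t | G ~ G,    G ~ PY(tau, sigma, G0),    G0 = Gamma(a0, b0),
```

so ties among the `lambda_t` cluster the epochs by innovation intensity and
the number of clusters `K` is inferred.  The package provides, for this
model:

* the data-augmented marginal **Gibbs sampler** (`fit_pyinar()`), with the
  homogeneous INAR(p) baseline (`fit_inar()`), compiled sweeps, and a
  Dirichlet prior on the thinning vector that puts all mass on the
  non-explosive region `sum(alpha) < 1`;
* **prior elicitation**: the concentration `tau` solved from a prior
  expected cluster count (`solve_tau()`), the Gamma base measure from a
  single scale `lambda_max` by a Kullback-Leibler reference argument
  (`elicit_base_measure()`), and the **elbow scan** over `lambda_max`
  (`elbow_scan()`) that locates where the posterior expected number of
  clusters levels off;
* the posterior **clustering point estimate** (`cluster_innovations()`):
  co-clustering dissimilarities `d_rt = Pr{lambda_r != lambda_t | y}`,
  classical multidimensional scaling, Ward dendrogram cut, and a
  permutation-matched confusion matrix against known labels;
* one-step-ahead posterior-predictive **forecasting** with rolling-origin
  cross-validated MAE comparison (`rolling_cv()`);
* a seeded simulator (`simulate_inar()`) for generalized INAR(p) series
  with finite Poisson-mixture innovations, recording each epoch's true
  component.

## Worked example

```r
library(pyinar)
set.seed(42)
sim <- simulate_inar(0.15, mixture_innovations(), T = 400)
sim$series
#> count_series: T = 400 observations, order p = 1
#>   range [0, 26], mean 9.197

h <- elicit_hyperparams(k0 = 6, sigma = 0.5, lambda_max = 60, n = 399)
h
#> Pitman-Yor hyperparameters: tau = -0.4192, sigma = 0.5, G0 = Gamma(a0 = 1.778, b0 = 0.05926)

fit <- fit_pyinar(sim$series, h, n_iter = 3000, n_burn = 1000, seed = 7)
fit
#> PY-INAR(1) fit: T = 400, 2000 retained draws
#>   posterior mean alpha: 0.1527
#>   number of clusters K: posterior mean 4.85, mode 3

sol <- cluster_innovations(fit, n_clusters = 3, truth = sim$components)
sol
#> cluster solution: 399 epochs cut into 3 clusters
#> confusion matrix (rows = predicted, matched; cols = truth):
#>      [,1] [,2] [,3]
#> [1,]  129   11    1
#> [2,]    4   97   18
#> [3,]    0   27  112
#> accuracy after optimal matching: 84.7%

set.seed(8)
point_forecast(predictive_draws(fit))
#> [1] 9
```

The series was simulated with thinning parameter 0.15 and an equal-weight
mixture of Poisson(1), Poisson(8) and Poisson(15) innovations.  The fit
recovers the thinning parameter (posterior mean 0.153), the posterior mode
of `K` lands on the true 3 components, and cutting the co-clustering
embedding at 3 clusters assigns 84.7% of the epochs to the correct mixture
component.  The point forecast is the posterior-predictive median of
`Y_401`.

A command-line interface wrapping the same functions ships in
`inst/cli/pyinar.R` with subcommands `simulate`, `fit`, `elbow`, `cluster`
and `forecast`; every run writes a JSON manifest (seed, configuration,
runtime) next to its outputs.

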