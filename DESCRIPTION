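Package: pyinar
Title: Semi-Parametric Bayesian INAR Models with Pitman-Yor Clustered
    Innovation Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the PY-INAR(p) model, a semi-parametric integer-valued
    autoregressive time-series model in which the Poisson innovation rates
    are clustered by a Pitman-Yor process placed at the top of the model
    hierarchy.  Provides the data-augmented marginal Gibbs sampler, prior
    elicitation for the Pitman-Yor hyperparameters (concentration from a
    prior expected number of clusters, base-measure parameters from a
    Kullback-Leibler reference argument) together with an elbow sensitivity
    scan, posterior point estimation of the innovation-rate clustering via
    co-clustering dissimilarities, metric multidimensional scaling and
    hierarchical clustering, and one-step-ahead posterior-predictive
    forecasting with rolling-origin cross-validation against the
    homogeneous INAR(p) baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
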