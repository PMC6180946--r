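Package: emcmed
Title: Single-Model Regression Framework for Causal Mediation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates direct, indirect, and total causal mediation effects
    and their closed-form model-based variances from the fit of a single
    linear outcome model, using the vector of changes in exposure-pathway
    coefficients (the essential mediation components) obtained by
    partitioning the coefficient covariance matrix. Supports multiple
    mediators with total and mediator-specific indirect effects, nonlinear
    exposure bases (polynomials, logs, linear splines), exposure-confounder
    and exposure-mediator interactions with the portion-eliminated variance,
    and nestedness diagnostics for the implied marginal model. Comparator
    estimators (Baron-Kenny product of coefficients, Sobel delta-method
    variance, case and residual bootstrap, Monte Carlo, parallel and serial
    multiple-mediator decompositions), closed-form omitted-covariate bias
    expressions, and a synthetic-data generator with simulation harnesses
    for variance-comparison and conditioning-set-bias studies are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
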