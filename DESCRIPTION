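Package: spanbvs
Title: Bayesian Variable Selection for Spatially Indexed Negative Binomial Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian negative binomial regression for spatially indexed count
    outcomes with high-dimensional, optionally group-structured predictors.
    Implements four shrinkage priors (horseshoe, spike-and-slab, grouped
    horseshoe, and a grouped spike-and-slab hybrid whose slab variance carries
    a horseshoe-type global and group scale), an intrinsic conditional
    autoregressive (ICAR) spatial random effect with queen-contiguity helpers,
    a Polya-Gamma augmented Gibbs sampler with closed-form full conditionals,
    variable selection via posterior inclusion probabilities or equal-tailed
    credible intervals, Geweke convergence diagnostics, and a simulation
    engine for lattice-based spatial count designs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Rcpp,
    MASS,
    igraph,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'spanbvs-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'priors.R'
    'fit.R'
    'diagnostics.R'
    'graph.R'
    'selection.R'
    'nbcore.R'
    'simulate.R'
    'io.R'
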