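Package: diallelh
Title: Bayesian Diallel-Cross Analysis of Sex-Specific Fitness and Mutation Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating sex-differential purging of mutation load
    from diallel-cross fitness data. Fits a Bayesian general linear mixed
    model by parameter-expanded Gibbs sampling to estimate the 4x4
    male/female by inbred/outbred genetic covariance matrix ("H matrix") of
    relative fitness among inbred strains, together with symmetric epistasis
    variances and class-specific residual variances. From the stored
    posterior it derives strain-level heterosis, standardized selection
    intensities against mutation-load alleles, and genetic correlations,
    each with kernel-density posterior modes, highest-posterior-density
    intervals and two-sided MCMC p-values, using cross-iteration resampling
    to decorrelate sex-averaged statistics. Includes a synthetic diallel
    data generator with saved ground truth, a full-sibling inbreeding
    coefficient recursion, Gelman-Rubin convergence diagnostics, and an
    end-to-end pipeline with reproducibility manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
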