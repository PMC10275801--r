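Package: twinirt
Title: Twin Variance Decomposition with Gene-Environment Interaction and
    Item-Level IRT Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian AE twin variance-decomposition models with
    gene-environment interaction, fitted either to standardized sum scores
    or to ordinal item-level data through a graded response model (GRM)
    measurement layer.  Supports unmeasured (AxE) interaction, measured
    moderators with log-linear variance moderation, and bivariate AE
    decompositions, estimated by adaptive Metropolis-within-Gibbs MCMC with
    within-sampler missing-data imputation, HPD intervals and DIC.  Includes
    a synthetic twin-family data generator with skew-inducing item banks for
    studying spurious interaction effects caused by ceiling-affected sum
    scores, plus phenotypic IRT tools (GRM/GPCM fitting by marginal maximum
    likelihood, test information, empirical reliability).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
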