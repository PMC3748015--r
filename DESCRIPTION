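Package: epibayes
Title: Fast Bayesian Genomic Prediction with Dominance and Epistasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide estimation of additive, dominance and pairwise
    epistatic marker effects with a fast Bayesian method based on the
    iterative conditional expectation (ICE) algorithm. Marker effects carry
    a mixture prior of a point mass at zero and a Laplace distribution, and
    each effect is set to its analytic posterior mean given phenotypes
    corrected for all other effects. Genotype covariates use the
    natural-and-orthogonal-interactions (NOIA) decomposition, so additive
    and dominance covariates are uncorrelated at every locus under the
    observed genotype frequencies, with epistatic covariates formed as
    element-wise products. The package also provides a forward-in-time
    mutation-drift simulator of a livestock population with half-sib
    family structure, quantitative trait architecture sampling with
    heritability calibration, translation of trait effects to the
    orthogonal scale, variance-component and accuracy reporting, and a
    scenario harness for replicated simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
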