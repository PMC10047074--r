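Package: dcinbreed
Title: Data-Cloned Errors-in-Variables Analysis of Inbreeding Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step maximum-likelihood analysis of inbreeding depression in
    non-pedigreed wild populations. Step one estimates individual inbreeding
    coefficients from multilocus codominant genotypes with a Gibbs sampler
    over latent identity-by-descent indicators, run under data cloning, and
    summarises each individual's posterior as a Beta measurement-error
    distribution. Step two fits hierarchical fitness models (a truncated and
    censored normal model for an individual Leslie-matrix growth rate,
    geometric models for adult survival and pupping intervals, and a negative
    binomial model for age at first reproduction) by data cloning with the
    inbreeding coefficient carried as a Beta-distributed latent covariate,
    and compares candidate models evidentially by Delta-BIC and Delta-AICc.
    Includes GenePop input, single-population genotype summaries (expected
    heterozygosity, Weir-Cockerham f, Brookfield null-allele frequency,
    multilocus homozygosity, identity disequilibrium g2), and synthetic-data
    generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    MASS,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
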