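Package: sfscoal
Title: Folded Joint Site-Frequency Spectra and Coalescent Demographic
    Inference for GBS SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for population-genetic analysis of reduced-representation
    (genotyping-by-sequencing) SNP data in structured plant populations:
    Watterson-theta locus whitelisting and missingness filters, per-locality
    diversity statistics (expected heterozygosity, nucleotide diversity,
    inbreeding coefficient), Weir-Cockerham F_ST, PCA with mean-dosage
    imputation, folded pairwise joint site-frequency spectra with
    hypergeometric projection, a structured-coalescent simulator for
    four-population divergence/migration models, and simulation-based
    composite-likelihood parameter estimation with
    expectation-conditional-maximisation cycles, AIC model selection and
    parametric-bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    vcfR,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
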