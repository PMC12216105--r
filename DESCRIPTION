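Package: demSBI
Title: Simulation-Based Machine Learning Inference of Two-Population
    Demographic Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring demographic parameters of two connected
    populations from genomic polymorphism data by simulation-based supervised
    learning. Simulates isolation-with-migration and secondary-contact
    demographic models through a coalescent backend, computes an extensive
    suite of per-locus summary statistics (site frequency spectra, linkage
    disequilibrium, identity-by-state and allele-frequency-conditioned
    identity-by-state segment lengths, haplotypic heterozygosity, Hudson's
    Fst, Dxy and the joint site frequency spectrum), trains per-parameter
    regressors (random forest, gradient-boosted trees, multilayer
    perceptron), benchmarks them against rejection, local-linear and
    neural-network approximate Bayesian computation, and explains
    predictions with permutation feature importance and Shapley values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table,
    ranger,
    xgboost,
    nnet,
    ggplot2,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with the msprime and tskit modules
    available on the PATH as 'python' (coalescent simulation backend).
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
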