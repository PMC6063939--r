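Package: phenoscore
Title: Benchmarking EHR Phenotyping Methods with Polygenic Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares electronic-health-record phenotype definitions (billing
    codes, clinical problem list, curated phenotyping algorithm) by the
    discriminative power of polygenic risk scores trained on each label set.
    Simulates polygenic case/control cohorts under a liability-threshold model
    observed through imperfect labeling channels, runs genotype quality control
    (call rate, minor allele frequency, exact Hardy-Weinberg test, sliding-window
    VIF linkage-disequilibrium pruning), per-variant logistic association with
    principal-component adjustment and genomic-control diagnostics, p-value
    thresholded polygenic scores under stratified cross-validation with folds
    shared across channels, and channel rankings by PRS case-control mean
    difference, AUC and odds ratio per standard deviation. Reads and writes
    PLINK bed/bim/fam and GWAS summary-statistic tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
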