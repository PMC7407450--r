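Package: gprisk
Title: Genomic Prediction of Binary Disease Risk Under the Liability
    Threshold Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic prediction of binary (case/control) traits
    from SNP genotypes, motivated by prediction of anterior cruciate
    ligament rupture in the Labrador Retriever. Reads and writes PLINK
    binary filesets; simulates cohorts with blockwise linkage
    disequilibrium, a polygenic liability with specified heritability and
    prevalence, and clinical covariates; applies marker quality control
    (call rate, minor allele frequency, exact Hardy-Weinberg test) and
    windowed LD pruning; fits five Bayesian whole-genome probit
    regressions (Bayesian ridge, Bayesian LASSO, Bayes A, Bayes B, Bayes
    Cpi) by Gibbs sampling with latent-variable augmentation; fits
    weighted subspace random forest, gradient boosted tree, naive Bayes
    and k-nearest-neighbour classifiers on SNPs selected within each
    training fold; combines base models by n-agreement voting or stacked
    supervision; and scores everything by repeated stratified 10-fold
    cross-validated AUC, including the analytic maximum AUC attainable
    given heritability and prevalence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    ranger,
    xgboost,
    e1071,
    class
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
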