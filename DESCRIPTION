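Package: snplca
Title: Latent Class Reclassification of SNP Genotype Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based reclassification of case/control cohorts from panels of
    additively coded SNP genotypes. Fits latent class models (finite mixtures of
    independent per-SNP multinomials) by EM with missing-data handling, selects
    the number of classes by parametric-bootstrap likelihood-ratio testing,
    explains the resulting clusters with genotype-subset classification trees and
    random forests, compares case and control cluster geometry by canonical
    discriminant analysis with Wilks' lambda MANOVA, and tests cluster-phenotype
    association with odds ratios, Woolf confidence intervals and backward-selection
    logistic regression. Includes a synthetic cohort generator with planted
    latent-class structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    randomForest,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    rpart,
    jsonlite,
    optparse,
    knitr,
    readr,
    withr
Config/testthat/edition: 3
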