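Package: cd4recover
Title: Phenotyping and Gene-Burden Association for CD4 Recovery on Suppressive Antiretroviral Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal phenotyping of CD4 lymphocyte recovery during
    virologically suppressive combination antiretroviral therapy (cART), and
    gene-level rare/common variant burden association for case-control response
    phenotypes. Provides visit-level imputation, smoothing and classification of
    semiannual cohort visits into treatment-response codes; good/poor responder
    calling with race/ethnicity frequency matching; univariate odds-ratio and
    forward stepwise logistic analysis of clinical covariates; VCF genotype
    ingestion with depth/quality masking, per-SNP quality statistics and
    ancestry principal components; and the Combined Multivariate and Collapsing
    (CMC) and Kernel-Based Adaptive Clustering (KBAC) burden tests with
    covariate adjustment and seeded adaptive permutation p-values. A synthetic
    cohort and genotype generator with planted effects makes the full pipeline
    testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
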