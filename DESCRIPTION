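Package: longgwas
Title: Functional GWAS for Longitudinal Traits via Random Regression Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association testing for longitudinal (repeatedly
    measured) traits using random regression test-day models with Legendre
    polynomial bases. Fits time-varied SNP effects either as a dosage
    covariate curve (fGWAS-C) or as per-genotype-class curves (fGWAS-F),
    tested by incremental Wald statistics against a pedigree-based polygenic
    random regression model with REML-estimated covariance components.
    Also provides the classical pseudo-phenotype strategies for comparison
    (accumulated EBV, deregressed proof, and GRAMMAR-style residual scans),
    a seeded forward-in-time simulator of pedigreed longitudinal phenotypes
    with a time-varied QTN, and multiple-testing utilities (Bonferroni,
    Storey q-values).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
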