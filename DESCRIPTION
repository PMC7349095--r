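Package: cnlohkit
Title: Tumor-Normal Copy-Neutral LOH, Somatic Variant, Copy-Number and
    Expression Analysis for Small Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated tumor-normal genomic analysis toolkit for small,
    genomically stable cancer cohorts. Implements two-tier somatic/LOH
    variant classification with a one-sided Fisher exact somatic p-value,
    coverage-conditioned tumor mutation burden, B-allele-fraction based
    loss-of-heterozygosity segmentation with cross-sample common-region
    intersection, circular binary segmentation of aCGH log2 ratios with
    noise-adaptive aberration calling and cohort recurrence analysis,
    copy-neutral LOH integration, rank-normalized differential expression
    with gene-set enrichment, and a synthetic paired tumor-normal cohort
    generator with a machine-readable truth set for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
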