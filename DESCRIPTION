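Package: tumorQTL
Title: Somatic-Aware cis-eQTL Mapping and Tumor-Purity Interaction
    Analysis for Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps cis expression quantitative trait loci (eQTLs) in tumor
    cohorts with a two-stage regression that adjusts expression for
    genotype principal components, hidden expression factors, sex, and
    somatic alterations (high-level copy-number events and inactivating
    mutations) before per-variant association testing. Gene-level
    inference uses adaptive permutations with a beta-distribution
    approximation of the null minimum p-value and Storey q-values.
    Detects genotype-by-tumor-purity interaction eQTLs and classifies
    them by purity tertile, tests somatic alteration-expression
    associations (somQTLs), partitions per-gene expression variance
    across model components, and scores intratumor heterogeneity from
    cancer cell fractions (MATH). A synthetic multi-omic cohort
    generator with a ground-truth effect registry makes every stage
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    vcfR
Config/testthat/edition: 3
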