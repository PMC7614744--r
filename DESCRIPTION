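Package: devpgs
Title: Developmentally Partitioned Polygenic Scores for Child Psychopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline linking cross-disorder polygenic
    risk to dimensional child psychopathology. Implements PLINK-style genotype
    and summary-statistic quality control, LD-score regression with block
    jackknife, genomic structural equation modelling (exploratory and
    confirmatory factor models on a genetic covariance matrix, and per-SNP
    common-factor GWAS), windowed SNP-to-gene annotation with SNP-wise mean
    gene tests and tissue gene-property regression, pre- versus postnatal
    differential-expression classification of genes per brain region,
    clumping-and-thresholding polygenic scores partitioned by developmental
    expression timing, and mixed-model phenotype association with quintile
    odds ratios and false-discovery-rate control. A synthetic-cohort
    generator with known ground truth makes every stage testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    lme4,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
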