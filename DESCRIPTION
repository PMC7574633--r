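Package: abotype
Title: ABO Blood-Group Inference from Tag SNPs with Case-Control
    Association and Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers ABO alleles (A, B, O01, O02), diplotypes, and blood
    types for diploid individuals from unphased genotypes at eight tag
    SNPs, and carries the inferred types through a complete case-control
    analysis: per-SNP Hardy-Weinberg equilibrium tests, allelic,
    genotypic and phenotypic association with Pearson chi-square
    statistics, Woolf odds-ratio confidence intervals and Bonferroni
    correction (total and sex-stratified), and an inverse-variance
    meta-analysis of per-study 2x2 blood-type tables with Cochran Q,
    I-squared and DerSimonian-Laird random effects, selecting the model
    by the I-squared greater-than-50-percent rule. A synthetic-cohort
    generator draws ABO haplotypes under Hardy-Weinberg proportions and
    expands them to tag-SNP genotypes (optionally with missingness and
    genotyping error, written as VCF), so the whole pipeline is testable
    without access to raw cohort genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
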