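Package: haplopair
Title: Two-Stage Case-Control SNP Association with Haplotype-Group Pair Tests
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-stage case-control association pipeline for biallelic SNP
    genotypes. Stage one applies sequential genotype quality control (call
    rate, minor allele frequency, Hardy-Weinberg equilibrium, autosome
    filter) and a single-SNP allelic (multiplicative) association test with
    odds ratios, Woolf confidence intervals and Pearson chi-square p-values,
    plus pairwise linkage-disequilibrium estimation (D, D', r-squared) by EM
    from unphased genotypes. Stage two selects nominally associated exonic
    variants, pairs them across a protein-protein interaction edge table,
    and tests each SNP pair with a pooled-allele multiplicative model and an
    additive model on risk-allele-count groups, with Bonferroni correction
    at both stages. Includes a synthetic case-control cohort generator with
    planted single-SNP and two-locus effects for power and calibration
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    vcfR,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
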