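Package: hlaquant
Title: Allele-Aware RNA and Protein Quantification of HLA Class I
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Personalized-reference proteogenomic analysis of HLA class I
    (HLA-A, HLA-B, HLA-C) expression in paired tumor/normal cohorts.
    Provides HLA nomenclature parsing and two-field (WMDA) reduction,
    read-compatibility genotyping with a minor-to-major homozygosity
    threshold, loss-of-heterozygosity and allele-imbalance calling from
    paired genotypes, personalized transcript references, allele-level
    RNA quantification, in-silico tryptic digestion with peptide
    specificity classification against sample genotypes, TMT reporter
    aggregation with pooled-reference ratios, and cohort statistics
    (paired differential expression with BH adjustment, allele-group
    frequency enrichment, RNA-protein variance partition). A synthetic
    cohort generator with recorded ground truth makes every stage
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
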