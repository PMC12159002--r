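Package: pgxcohort
Title: Star-Allele Diplotyping, Phenotype Translation and Actionability
    Scoring for Exome Pharmacogenomic Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts pharmacogenomic (PGx) information from exome-style
    cohort data: calls star-allele diplotypes from unphased VCF genotypes
    with population-frequency resolution of phasing ambiguity and
    copy-number-aware deletion/duplication handling, gates genes on
    sequencing depth at haplotype-defining positions, translates
    diplotypes to CPIC-style phenotypes (metabolizer classes, activity
    scores, function classes, carrier-risk labels), applies a binary
    phenotype- and HLA-allele actionability map, and produces
    ancestry-stratified phenotype frequency tables compared against
    reference populations. A seeded synthetic-cohort generator emits
    truth tables, VCFs, depth, copy-number and HLA files emulating an
    admixed pediatric exome cohort so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    methods,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
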