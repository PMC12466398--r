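Package: equifix
Title: Genomic Diversity, Inbreeding and Fixed-Variant Scans for Small
    Whole-Genome Sequenced Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream whole-genome resequencing analysis for small diploid
    cohorts, motivated by native horse breed studies: variant summarization by
    chromosome and functional consequence class, observed and expected
    heterozygosity, sliding-window nucleotide diversity, genomic relationship
    matrix (GRM) construction with three genomic inbreeding estimators (F_GRM,
    F_HOM, F_UNI) and GRM-based principal component analysis, a breed-specific
    fixed-alternative-variant filtering cascade with prioritized candidate gene
    selection, and segregation scanning of a Mendelian trait-variant catalog.
    Includes a deterministic synthetic cohort simulator (annotated multi-sample
    VCF plus ground-truth tables) so every stage is testable without external
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
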