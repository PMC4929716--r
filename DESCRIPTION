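Package: VariantSieve
Title: Rule-Based Filtration and Prioritization of Annotated Exome Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A seven-step filtration cascade for annotated whole-exome
    variant tables: restrict to exonic variants, drop synonymous and
    nonframeshift classes, remove variants common in the 1000 Genomes
    Project or the NHLBI Exome Sequencing Project (ESP6500), remove
    non-conserved positions by GERP score, remove tolerated missense
    changes by FATHMM score, and link surviving genes to known disorders
    by keyword matching against local gene-disease tables. Consumes
    ANNOVAR/wANNOVAR-style tab-delimited annotation exports, emits a
    ranked candidate shortlist and a stepwise attrition report, and
    ships a deterministic synthetic-table generator so every filter
    count is analytically predictable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
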