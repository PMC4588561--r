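Package: kinomeHFI
Title: High Functional Impact Variant Analysis for Targeted Kinome
    Sequencing
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Consensus prioritization of high functional impact (HFI)
    nucleotide variants from annotated targeted kinome sequencing of
    tumor biopsies. Classifies each variant by a consensus rule over
    Mutation Assessor category, SIFT score and a kinase-specific
    deleteriousness verdict (or structural stop-gain / stop-loss /
    frameshift status), aggregates HFI calls into a gene-by-sample
    matrix, computes length-normalized variant loads per kinase group,
    and compares gene-level variant frequencies between clinical
    subgroups with exact tests (two-sided Fisher, Wilcoxon rank-sum)
    under Bonferroni correction. Includes a somatic-germline
    co-occurrence screen, technical-replicate concordance metrics, and
    a seeded synthetic-cohort generator so every pipeline stage can be
    exercised without access to patient-level sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    VariantAnnotation,
    GenomicRanges,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
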