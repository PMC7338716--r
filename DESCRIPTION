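Package: VariantTriage
Title: Three-Tier Triage and Clinical-Style Reporting of Annotated Germline Variants
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable triage engine that turns annotated germline variant
    tables (VCF or delimited platform exports) into categorized clinical-style
    reports. Implements a variant-centric first tier driven by ClinVar aggregate
    interpretation signatures, a gene-centric second tier combining virtual gene
    panels with ACMG/AMP evidence combination and a nine-predictor in-silico
    deleteriousness consensus, and a third tier that forwards rare
    loss-of-function variants of uncertain significance to the report annex.
    Includes quality-based retention rules with a dual all-variants /
    high-confidence pass, PharmGKB evidence-level routing between the main
    report and the annex, cohort summary statistics, and a synthetic-cohort
    generator with planted ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
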