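Package: CNVtriage
Title: Clinical Triage of Chromosomal Microarray CNV and UPD Calls in
    Neurodevelopmental Disorder Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the post-calling interpretation of chromosomal
    microarray results in clinical cohorts of children with autism spectrum
    disorder or unexplained intellectual disability and developmental delay.
    Implements the standard clinical funnel: a reporting threshold on segment
    size and probe support, rarity filtering against an ethnically matched
    control panel and a reference CNV frequency set using dosage-matched
    reciprocal overlap, segmental-duplication masking, five-tier ACMG-style
    classification against a curated syndrome/candidate-gene knowledge base,
    trio-based de novo and parent-of-origin assignment, and cohort-level
    diagnostic-yield stratification with exact two-by-two tests. Ships a
    subject- and variant-level reference cohort of 410 probands together with
    a seeded synthetic trio-cohort generator so every pipeline stage can be
    exercised and validated without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    knitr,
    rmarkdown
biocViews: CopyNumberVariation, GenomicVariation, VariantAnnotation,
    Classification, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
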