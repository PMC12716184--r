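Package: omicspod
Title: Benchmark Dose Modeling and Mechanistic Point-of-Departure Analysis
    for Multi-Dose Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns multi-dose omics matrices (expression, promoter
    methylation, targeted assays) into gene-level benchmark doses
    (BMD/BMDL/BMDU) by fitting a family of dose-response models with AIC
    selection or Akaike-weight model averaging, aggregates them into
    transcriptome-wide points of departure (twPOD), correlates
    model-predicted dose-response curves across genes and omics layers to
    build co-dose-dependency networks with protein-protein interaction and
    transcription-factor overlays, and maps dose-dependent genes onto
    adverse outcome pathways (AOP) via key-event enrichment, KE-KE network
    assembly, per-KE biomarker prioritization, and hazard-class rollups.
    Includes a ground-truthed synthetic fixture generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph,
    cluster,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
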