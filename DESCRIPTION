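Package: ailqtl
Title: Time-Series QTL Mapping in Advanced Intercross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Single-marker QTL mapping of weekly body-weight time series in
    advanced intercross lines (AILs) between closely related inbred founders.
    Provides per-week genome scans with LOD curves, effective-number-of-tests
    (simpleM) Bonferroni thresholds, 1.5-LOD-drop support intervals aggregated
    across weeks, a two-stage selective-genotyping design (array subset plus
    targeted assays at top markers), candidate-gene prioritization from variant
    consequences, differential expression and pathway membership, and
    position-weight-matrix scanning of upstream regions for carbohydrate
    response elements (ChoRE). Includes a pedigree-based AIL simulator with
    Haldane recombination so every stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
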