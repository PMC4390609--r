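Package: miRcons
Title: Consensus miRNA Target Prediction over a Common 3'-UTR Sequence Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a complete isoform-level 3'-UTR sequence space from a
    genome and its transcript annotation (with a fixed-length downstream
    proxy for missing or short UTRs), predicts miRNA target sites with
    three heterogeneous engines (exact seed-match scanning, complementarity
    alignment with G-U wobble, and nearest-neighbour duplex free-energy
    minimisation), ingests experimentally validated miRNA-gene pairs from
    tiered source databases, and combines per-engine predictions that hit
    the same genomic position into a calibrated consensus weighted score.
    Per-engine weights are precision-above-score curves estimated against
    validated pairs and made monotone by isotonic regression. Includes ROC
    evaluation of engines and consensus, stratified by reliability tier,
    and a seeded synthetic-fixture generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
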