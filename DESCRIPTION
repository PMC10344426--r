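Package: crquant
Title: Quantitative Analysis of CUT&RUN Histone-Mark and Transcription-Factor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spike-in-free quantification pipeline for CUT&RUN experiments
    comparing low-level histone-mark enrichment between conditions. Provides
    TMM normalization on reads-in-peaks with a final per-million scale factor,
    sliding-window differential enrichment testing with negative-binomial
    exact tests, SICER-style broad-domain (Polycomb domain) calling with
    score/length/gap filters, coverage-ratio comparison of narrow peaks
    against broad domains, depth-matched genome-bin density statistics,
    HOMER-style peak annotation and gene-class binding fractions, matched
    shuffled background controls, and a synthetic fragment simulator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    jsonlite
Config/testthat/edition: 3
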