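Package: restpoise
Title: Integrative Audit of REST-Dependent Chromatin Poising Independent of Polycomb
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for testing whether REST-bound neuronal genes
    are transcriptionally poised independently of Polycomb repressive
    complex 2. Provides RE1 motif scanning with exact position-weight-matrix
    p-values, reciprocal peak/domain overlap statistics, domain-restricted
    differential histone-mark comparison between genotypes with a
    treatment/control swap procedure, bivalent promoter classification,
    regression of expression changes on chromatin-mark changes, delta-delta
    Ct relative quantification with error propagation, and affinity
    purification replicate filtering. A synthetic-data module generates
    genomes with planted RE1 motifs, ChIP coverage tracks, expression
    counts, qPCR plates and peptide tables with known ground truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
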