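Package: h33dyn
Title: Downstream Analysis of Inducible H3.3 Incorporation Time-Course Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of time-resolved ChIP-seq
    (Time-Seq) of Doxycycline-inducible tagged histone H3.3 together with
    matched RNA-seq, covering binned coverage tracks with global-reference
    normalization, anchor-centered incorporation profiles and metagene curves,
    TSS-flanking gene window scores, binding-expression coupling statistics,
    differentiation state-retention analysis, an early-binding to
    late-expression contingency procedure, CyTOF marker normalization, and a
    fully deterministic synthetic-experiment generator that emulates the
    statistical structure of such experiments for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
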