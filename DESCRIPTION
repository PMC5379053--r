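Package: tecrm
Title: Transposable-Element Cis-Regulatory Module Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering and characterizing cis-regulatory modules
    encoded by transposable elements (TEs). Implements clustering of
    transcription-factor binding sites, subfamily-level enrichment statistics
    (log odds ratios with hypergeometric significance), position weight matrix
    scanning with exact score-distribution p-values, information-content-guided
    motif mutagenesis design, LTR retroelement insertion-time dating under the
    Jukes-Cantor model, binned epigenomic metaprofiles, and quantification of
    regulatory potential from luciferase and barcoded reporter (MPRA) data.
    Ships a synthetic-data generator with known ground truth so the whole
    pipeline is testable end to end.
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
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
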