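Package: gliEnhancers
Title: Classification of Hedgehog-Responsive GLI Enhancers from Differential Chromatin Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for identifying and classifying GLI transcription-factor
    binding regions (GBRs) by their Hedgehog-dependent chromatin response.
    Implements differential H3K27ac enrichment testing between conditions with
    an empirical-Bayes moderated t-statistic, a simplified fixed-window Poisson
    peak caller, three-way classification of GLI binding regions (Stable,
    HH-sensitive, HH-dependent), permutation tests for enrichment near
    target-gene transcription start sites, position-weight-matrix scanning with
    motif presence/quantity/quality statistics, chromatin-accessibility
    comparisons, and a seeded synthetic-data generator with planted ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
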