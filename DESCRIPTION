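Package: arpscreen
Title: Transcriptional Profiling of the Aneuploidy Response Pattern and
    Consensus Marker Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for transcriptional responses to chromosome
    gains in model aneuploid human cell lines. Implements single-channel
    microarray-style normalization (log2 transform, median centering, probe
    and replicate median summarization), per-contrast fold-change profiles
    with Welch t-tests, Benjamini-Hochberg adjustment and a Grenander-based
    local false discovery rate, rank-based pathway (annotation) enrichment
    with scores in [-1, 1] and two-comparison pairing, generalization of
    annotations into pathway classes, Spearman distance matrices with
    hierarchical clustering, and a consensus aneuploidy-marker screen with
    stress-condition overlap flagging. Ships a synthetic-data generator that
    plants chromosome-dosage effects, a shared pathway-response signature
    with cell-line-variable gene membership, a fixed marker panel and stress
    profiles, together with machine-readable ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
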