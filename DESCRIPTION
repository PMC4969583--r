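Package: imune
Title: Discovery of Disease-Specific Antibody-Binding Motifs from Peptide
    Display Repertoires
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the IMUNE approach to discriminative peptide motif
    discovery from deep-sequenced peptide display library screens. Per-sample
    peptide repertoires are reduced to non-redundant sets, the space of short
    amino-acid patterns (3-5 defined residues interleaved with wildcards, span
    up to 10) is counted exhaustively in every sample, and patterns enriched in
    case samples but not in controls are retained using Poisson tail
    probabilities, standard-deviation thresholds, or rank-order (ROC)
    separation. Retained patterns are clustered into set-valued motifs via
    PAM30 alignment of motif seeds, and motifs are scored per sample with a
    best-five-defined-positions enrichment convention that supports simple
    panel-based classification. A synthetic cohort generator with planted
    motifs makes the whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
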