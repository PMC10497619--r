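Package: barrierscreen
Title: Sort-Seq Screening Analysis for Barrier-Type DNA Elements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis toolkit for pooled sort-seq screens of barrier-type
    (insulator) DNA elements challenged inside lamina-associated domains.
    Covers design of the screening library (ranked CTCF-binding sites, MIR
    repeats stratified by distance to LAD boundaries, random controls, type
    IIS site exclusion, coverage arithmetic), simulation of the silencing
    screen (all-or-none switching plus graded reporter decay, FACS gating,
    PCR/sequencing noise, plasmid-pool baselines), read mapping to the
    element library (quality/linker trimming, affine-gap Smith-Waterman,
    best-hit deduplication and post-alignment filters), enrichment calling
    against the plasmid library (relative abundance, fold change, Welch
    t-tests, volcano/heatmap exports), sequence-feature statistics (GC
    content, degenerate IUPAC motif counts, information-content logos), and
    flow-cytometry normalization with silencing-kinetics fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
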