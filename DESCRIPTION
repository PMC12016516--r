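Package: apmsrank
Title: Scoring, Ranking and Network Assembly for AP-MS Spectral Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an affinity purification-mass spectrometry (AP-MS)
    interactome scoring pipeline for spectral-count data: per-bait enrichment
    of tagged purifications over parental (mock) controls by a one-sided
    Fisher exact test with Benjamini-Hochberg correction and fold-change
    thresholds, a five-tier confidence rank for each significant bait-prey
    association, threshold rescue for baits that narrowly miss the
    fold-change cutoff, and assembly, filtering, intersection and export
    (TSV, SIF, GraphML) of rank-weighted, condition-tagged bait-prey
    networks. A synthetic-data generator produces overdispersed AP-MS count
    experiments with planted true partners, sticky resin binders and
    undetectable proteins for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
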