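Package: ssvepnet
Title: Coherence-Based Functional Network Topology of Steady-State Visual
    Evoked Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted functional connectivity networks from
    multichannel steady-state visual evoked potential (SSVEP) recordings and
    relates their topology to the strength of the evoked response. Epochs are
    extracted from artifact-free segments, narrow-band magnitude-squared
    coherence is computed at the stimulus frequency for every electrode pair,
    per-epoch matrices are averaged into a whole-head network, and a
    sparsity-value search prunes spurious weak edges while keeping every
    subject's network free of isolated nodes. Edges are then classified by
    the sign and significance of the across-subject correlation between
    connection strength and stimulus-band signal-to-noise ratio, and weighted
    graph metrics (Onnela clustering coefficient, harmonic-mean
    characteristic path length, global and local efficiency) are correlated
    with the SSVEP response. Includes a synthetic-cohort generator with
    known entrainment factors and planted coupled edges, an edge-wise
    two-group permutation test, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
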