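Package: typetracker
Title: Backpropagation of End-Point Cell Types Along Tracked Lineage Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers per-cell types over time in time-lapse recordings of
    intestinal organoids by propagating end-point antibody-staining
    identities backward along tracked lineage trees, and quantifies the
    resulting spatiotemporal differentiation program. Provides readers and
    writers for tracked-nuclei tables and a tracker-style JSON dialect,
    marker-panel cell-type calling, one-to-one min-cost matching of stained
    to tracked end-point cells, rule-based type backpropagation with
    transition events, crypt-villus axis fitting and arc-length projection,
    neighbor-score adjacency graphs with neighbor and sister separation
    rates, lineage-level statistics, and a synthetic crypt generator with
    ground-truth commitment events.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
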