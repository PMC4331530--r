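Package: dualflow
Title: Dual-Flow Network Propagation for Disease Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate disease genes on protein-protein
    interaction networks by signed network propagation: known disease genes
    inject positive flow and non-disease essential (housekeeping) genes
    inject negative flow; candidates are ranked by their steady-state net
    flow. Includes breadth-first shell statistics comparing the proportion
    of non-disease essential proteins around protein classes, a
    leave-one-out cross-validation harness with chromosome-local candidate
    lists, enrichment scoring, ROC/AUC reporting, and a synthetic network
    generator with planted disease modules, an essential hub core, and
    decoy hubs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
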