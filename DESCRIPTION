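Package: netmodule
Title: Network Medicine Toolkit for Drug-Disease Proximity and Disease
    Module Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies drug effects on a disease neighborhood of the
    protein-protein interactome. Implements the closest network proximity
    between drug targets and disease genes with a degree-matched random
    null model and z-score classification, DIAMOnD connectivity-based
    disease-module detection with a sliding-window validation stopping
    rule, local functional enrichment (Fisher/EASE) with enrichment-map
    construction, attack-vulnerability (percolation) analysis of the
    resulting networks, and single-sample gene-set enrichment (ssGSEA)
    scoring of paired treatment expression data. Ships a synthetic-data
    generator that plants a dense disease module, proximal and distal
    drugs, enriched gene sets and treatment-responsive expression so the
    whole pipeline can be exercised with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
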