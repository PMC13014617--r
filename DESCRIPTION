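Package: micrometab
Title: Scoring Disease-Metabolite Associations from Gut Microbial Abundance
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies disease-metabolite association strength from changes in
    gut microbial relative abundance. For each disease-metabolite pair the
    association score sums the disease-versus-healthy difference in median
    species-level relative abundance over the species that produce the
    metabolite, attaches a paired t-test confidence p-value with
    Benjamini-Hochberg false discovery rate control, nominates
    disease-ameliorating (beneficial) metabolite candidates and biomarker
    candidates, benchmarks score directions against literature-reported change
    directions, and builds weighted disease-metabolite and metabolite-gene
    association networks with Cytoscape-compatible export. Includes a
    compositional synthetic cohort simulator with planted effects for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
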