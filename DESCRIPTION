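Package: homolineage
Title: Homology-Index Lineages, Ortholog/Paralog Events and Gene-Tree
    Discordance for Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a homology index (HI) on [0,1] for protein pairs from
    pairwise alignment statistics, groups genes into nested homologous
    groups by sweeping HI thresholds (single-linkage connected components),
    classifies the resulting group-splitting events into orthologous and
    paralogous events from gene/species count dynamics, builds HI-scale
    dendrograms, per-species orthology trees and taxonomy trees, quantifies
    their discordance with the Robinson-Foulds metric and a Monte-Carlo
    percentile against random topologies, and derives a species-species
    network weighted by a shared-gene F-measure (CI index). Includes a
    seeded gene-family simulator (speciation, duplication, substitution)
    providing ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
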