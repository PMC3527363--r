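Package: netKB
Title: Query and Visualization Engine for Documented Biomolecular Interaction Networks
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A file-backed knowledgebase of documented biomolecular
    interactions (modeled on NCBI Interaction GeneRIFs) with a query engine
    and GraphViz DOT renderer. Multi-gene, multi-group queries are resolved
    through Entrez-style identifiers, official symbols and synonyms, expanded
    across HomoloGene-style ortholog groups, extracted under four
    network-radius modes (radius 0, radius 0 with intermediates, radius 1,
    radius 2), filtered by interaction type and annotation status, partitioned
    into ortholog-stacked compound nodes, and rendered to DOT with typed edge
    encodings, query-group coloring, auto-generated legends and node/edge
    hyperlink maps. Includes a seeded synthetic-fixture generator with
    scale-free degree structure, a keyword lookup tool over gene annotation,
    and a crowdsourcing-style submission pipeline with redundancy checking
    and a revertible change history.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
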