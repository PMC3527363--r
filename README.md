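# netKB

A query and visualization engine for knowledgebases of **documented
biomolecular interactions** — the kind of corpus built from curated
literature annotations, where every edge between two genes (protein–protein
binding, protein→DNA regulation, genetic interaction) is backed by PubMed
citations. It is written for systems biologists who want to go from a list
of gene symbols to a readable, clickable interaction drawing, and for
curators who want to add missing interactions to such a corpus without
introducing redundancy.

Everything is file-backed (four TSV tables: interactions, gene annotation,
ortholog groups, change history) and ships with a seeded synthetic-corpus
generator, so no database server or network access is ever needed.

## The core model

Documented interaction networks are scale-free: most genes have a couple of
documented partners, a few hubs have hundreds. netKB controls the drawing's
complexity with two dials.

**Network radius.** For a query set *Q* over the record set *E*, the four
modes select:

| mode | edges drawn |
|---|---|
| radius 0 | { e ∈ E : both endpoints ∈ Q } |
| radius 0 + intermediates | radius 0 ∪ { x–q : q ∈ Q, x an *intermediate* } |
| radius 1 | { e ∈ E : ≥ 1 endpoint ∈ Q } |
| radius 2 | radius 1 ∪ { e ∈ E : ≥ 1 endpoint ∈ N₁ } |

where an **intermediate** is a non-query gene whose interactants include at
least two *distinct* members of *Q*, and *N₁* is the set of non-query
endpoints of radius-1 edges. Radius is prescribed relative to the query
genes, not the graph-theoretic radius of the result. Edge direction (only
protein→DNA edges are directed, regulator → target) never affects
membership but is preserved in the drawing.

**Orthology.** By default each query gene is expanded to its full ortholog
group (HomoloGene-style shared group id), and orthologs with documented
interactions that appear in the result are drawn as one *stacked* compound
node — putting what is known in mouse next to what is known in human.
Alternatively the query can be confined to a single organism, which
disables expansion and keeps only records with both endpoints in that
taxon.

Results render to GraphViz DOT (sfdp layout) with one *hypernode* per gene
(molecular role implied by each edge's type: black line = protein–protein,
red arrow = protein→DNA), colored query-group borders, an auto-generated
legend, and a URL map linking nodes to Entrez-style gene pages and edges to
interaction record anchors.

## Worked example

```r
library(netKB)

# a synthetic corpus shaped like a pluripotency-factor query: 6 hub genes
# with orthologs in 3 taxa, private and shared partners, background edges
fx <- generateComplexityFixture(seed = 1)
fx$kb
#> Knowledgebase: 216 interactions, 216 genes (3 taxa), 6 ortholog groups, 0 history events

# two overlapping query groups, radius 0 with intermediates, all orthologs
spec <- parseQuery(fx$queryString, fx$kb,
                   resolutionOrganism = fx$resolutionTaxon,
                   radiusMode = "R0_INTERMEDIATES")
spec
#> QuerySpec: 2 group(s), radius R0_INTERMEDIATES, all orthologs
#>   Query Group 1: 1001, 1004, 1007, 1010
#>   Query Group 2: 1007, 1010, 1013, 1016

graph <- extractSubgraph(spec, fx$kb)
graph
#> InteractionGraph: 30 nodes, 30 merged edges
#>   roles: query=18, intermediate=12

partition <- buildPartition(graph, fx$kb, spec)
partition
#> CompoundPartition: 5 stack(s), 18 singleton(s)

doc <- toDot(graph, partition, spec, fx$kb)
doc
#> DotDocument: 6286 characters of DOT, 65 mapped URLs, 6 legend items
renderDot(doc, "dot", "query.dot")
```

The 18 query nodes are the 6 hubs expanded across their 3-taxon ortholog
groups; the 12 intermediates are the shared partners touching at least two
query members. The same query at radius 1 across all orthologs yields 186
nodes — the two dials cut the drawing by a factor of six. The legend lists
one entry per edge encoding present plus one per named query group:

```
               glyph                       label
1   solid black line protein-protein interaction
2    solid red arrow    protein->DNA interaction
3   dashed blue line         genetic interaction
4 dotted gray50 line           other interaction
5 box colored #0072B2              Query Group 1
6 box colored #D55E00              Query Group 2
```

The query grammar is `query := group ("/" group){0,2}`,
`group := token ("," token)*` — at most three groups, tokens being gene
ids, official symbols or unambiguous synonyms.

A command-line tool wrapping the same functions is installed at
`system.file("cli", "netkb", package = "netKB")`, with subcommands
`query`, `fixture`, `lookup`, `submit-check`, `submit` and `revert`.

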