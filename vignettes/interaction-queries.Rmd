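---
title: "Querying and drawing documented biomolecular interaction networks"
author: "netKB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Querying and drawing documented biomolecular interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netKB)
```

## The problem

Curated corpora of documented biomolecular interactions — protein–protein
binding, protein→DNA regulation, genetic interactions — grow quickly and
unevenly across model organisms. Two practical obstacles stand between a
bench scientist and this knowledge. First, the interaction graph around any
interesting gene is scale-free: a handful of hub genes carry hundreds of
documented partners, so a naive "show me everything" query is unreadable.
Second, coverage differs by organism, so what is known about a gene in
mouse may be exactly the clue missing for its human ortholog.

netKB is a file-backed query and visualization engine for such corpora. It
resolves gene identifiers, extracts a query-scoped subgraph at a chosen
*network radius*, stacks orthologs into compound nodes, and emits GraphViz
DOT with typed edge encodings, query-group coloring, a generated legend,
and node/edge hyperlink maps. A submission pipeline lets users add
literature-documented interactions, with redundancy checking and a
revertible change history.

## The data model

Four tab-separated tables define a knowledgebase (see
`?loadKnowledgebase` for the exact columns):

* **interactions** — one row per documented interaction: two Entrez-style
  gene ids with their taxa, a type (`PP`, `PD`, `GI`, `OTHER`), a
  direction (`AB` for protein→DNA, `NONE` otherwise), one or more
  supporting PubMed ids, an optional submitter, and an annotation status
  (`curated` or `user`).
* **gene_info** — taxon, official symbol, synonyms, description and GO
  terms per gene.
* **homologene** — ortholog groups, one row per member.
* **history** — the append-only log of user submissions.

Three modeling invariants are enforced on load and construction: every
interaction cites at least one PubMed id; only protein→DNA interactions
are directed (regulator → target); and user-submitted records always carry
their submitter's name. Genes referenced by interactions but missing from
`gene_info` are tolerated with a warning and labeled by raw id — real
interaction exports contain such orphans.

## Network radius

Radius here is the prescribed graph distance with respect to the query
genes, not the graph-theoretic radius of the drawing:

* **radius 0** — only interactions between members of the query list;
* **radius 0 with intermediates** — radius 0, plus every non-query gene
  that interacts with at least two *distinct* query members
  (an *intermediate*), with its query-side edges only;
* **radius 1** — every interaction touching a query member;
* **radius 2** — radius 1 plus every interaction touching a radius-1
  interactant (including neighbor–neighbor edges).

Two decisions here were genuinely open and are worth recording. An
intermediate must touch two *distinct* query genes: two separate records
linking it to the same query gene do not qualify, and after ortholog
expansion each expanded gene counts separately (members are genes).
Intermediate–intermediate edges are excluded — the mode shows query↔query
and query↔intermediate interactions only — whereas radius 2 *does* include
edges among first-shell neighbors, because it is defined over all
interactions of radius-1 interactants. Edge direction never affects
neighborhood membership (the target of a query gene's protein→DNA arrow is
a neighbor) but is preserved in the drawing.

Queried genes with no surviving interactions are kept as isolated nodes:
a user who queries a gene with no documented results should see that
absence rather than wonder whether the query was dropped.

```{r radius}
fx <- generateComplexityFixture(seed = 1)
spec <- parseQuery(fx$queryString, fx$kb,
                   resolutionOrganism = fx$resolutionTaxon,
                   radiusMode = "R0_INTERMEDIATES")
extractSubgraph(spec, fx$kb)
```

## Queries, groups, and identifier resolution

A query is up to three '/'-separated groups of comma-separated tokens;
groups are color-coded in the output and named in the legend ("Query Group
1..3" unless renamed). Tokens resolve with precedence numeric id >
official symbol > synonym, case-insensitively, scoped to an organism when
one is given. A token matching two or more genes is reported ambiguous
with all candidates — never silently picked — and a query is only accepted
when every token resolves. We relax the strict "symbols require an
organism" web-form rule to "an organism is required only when the match is
actually ambiguous"; a purely numeric token is always treated as a gene
id, so a gene whose official symbol is all digits is reachable only by id.

By default queries run in all-ortholog mode: each query gene is expanded
to its full ortholog group, and expanded genes inherit the group
membership of the gene that pulled them in. Setting an organism confines
both resolution and results to one taxon and disables expansion; records
are kept only when *both* endpoints belong to that taxon, so single-species
drawings contain only that species' genes.

## Ortholog stacking

Orthologs are drawn as one stacked (compound) node only when each member
has a documented interaction that actually appears in the resulting graph.
Members failing that visibility condition — including isolated query
genes — render as plain singletons. Paralogs within one taxon that share a
group do stack: group membership is the only criterion. Stack members are
ordered by taxon id, which also picks the stack's display anchor
deterministically.

## Rendering

Nodes are *hypernodes*: one node per gene regardless of how many molecular
roles its edges imply; an incident black line means the protein, an
incident red arrow into the node means the gene's DNA. Default encodings:
protein–protein = solid black undirected, protein→DNA = solid red arrow,
genetic = dashed blue, other = dotted gray; all overridable through a flat
key=value style file (`?readStyleConfig`). The group palette defaults to a
colorblind-safe set; a node in several groups takes the lowest group's
color plus a double-periphery marker, since no convention exists for
multi-group nodes.

The document requests the `sfdp` layout engine — the multiscale
force-directed engine suited to scale-free graphs. Because `sfdp` ignores
cluster subgraphs, stacks are emitted as single record-shaped nodes with
one port per member (ports carry per-member URLs in the URL map) rather
than as clusters. Duplicate documentation of the same interaction (same
unordered pair, type and direction) merges into one edge carrying every
supporting record id; node URLs use an Entrez-style gene template and edge
URLs a local `record://<ids>` anchor template, overridable when a record
server exists. Submitter names of user-submitted records surface in the
edge tooltip and URL map. Output is deterministic: nodes sort by (taxon,
gene id), edges by endpoints and type, and identical inputs yield
byte-identical DOT. `renderDot()` writes DOT directly and shells out to
GraphViz for SVG/PDF/GIF+CMAP only when the engine is installed.

## The synthetic corpus generator

`generateFixture()` emulates the documented-interaction corpora the engine
targets: preferential-attachment endpoint sampling (degree + 1 weights)
reproduces the scale-free shape — a few hubs, many low-degree genes — and
the defaults spread genes over three taxa (human/mouse/rat taxon ids),
place 30% of genes in cross-taxon ortholog groups of 2–3, and draw types
as 60% PP / 20% PD / 15% GI / 5% OTHER, proportions chosen once as
realistic for GeneRIF-derived corpora. Self-interactions are permitted and
drawn as self-loops. `generateComplexityFixture()` builds the structured
variant used to demonstrate complexity control: hub genes with full
ortholog groups in every taxon, mostly-private per-taxon partners (Poisson
mean 8 per hub per taxon), a few partners shared between hubs (the
intermediates, 4 per taxon), and hub-free background edges; the expected
node counts of the four panels (roughly 160 > 55 ≥ 30 > 10) make the
complexity ordering hold by construction rather than by tuning.

What the generator does *not* emulate: literature-driven correlation
between annotation fields and connectivity, realistic symbol nomenclature,
taxon-biased coverage, or multi-record documentation bursts around famous
genes. Passing tests therefore demonstrate the engine's algebra — set
definitions, partition conditions, determinism — on graphs of realistic
shape, not fidelity to any particular real corpus.

## Numerical and procedural choices

* **Scales.** The property suites run on 200 random fixtures of up to 120
  genes and 400 interactions for extractor/oracle equivalence, and 100
  fixtures for the intermediate, stacking, ordering and submission
  properties — large enough that each property is exercised across dense,
  sparse and empty regimes.
* **Determinism.** Every generator call is a pure function of its
  arguments including the seed; the global RNG state is saved and
  restored around it. Tables are written in canonical sort order so
  write∘load is the identity byte-for-byte.
* **Ties and degenerate inputs.** Empty query results are valid graphs
  (query nodes only); an empty include-type set is rejected as a
  configuration error rather than silently returning empty graphs;
  trailing commas in queries are forgiven but empty groups between
  slashes are errors.
* **Redundancy scope.** A submission is redundant when an existing record
  has the same unordered pair and type — direction included for
  protein→DNA, whose reversal is a different regulatory claim — and PubMed
  ids are deliberately ignored, so a new citation for a known interaction
  warns but can be force-committed as additional documentation.
* **Revert semantics.** `revertTo()` truncates the history to the target
  state by default, making commit∘revert restore the previous
  serialization byte-for-byte; `log = TRUE` instead appends a `revert`
  event for an audit trail, and `replayHistory()` understands both.

## Limitations

No radius beyond 2, no shortest-path or centrality analytics, no
interaction scoring or functional-association prediction, no fuzzy symbol
matching, no GO-graph traversal (terms are opaque strings), and no web
front end — the record-page URLs are templates awaiting a server. RNA-level
interactions have no dedicated type; they travel as `OTHER` with the raw
type text on the record.
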