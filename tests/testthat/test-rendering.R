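# DOT emission is validated with the grammar checker in helper-oracle.R:
# node statements in the main body must equal |stacks| + |singletons| and
# edge statements |merged edges|; the legend lives in a cluster subgraph.

renderAll <- function(kb, spec) {
    g <- extractSubgraph(spec, kb)
    p <- buildPartition(g, kb, spec)
    list(graph = g, partition = p, doc = toDot(g, p, spec, kb))
}

test_that("a one-edge graph renders one styled edge and two nodes", {
    kb <- hKb(recs = list(hRec(1, 101, 102)),
              genes = list(hGene(101, symbol = "ABC"), hGene(102)))
    r <- renderAll(kb, querySpec(c(101, 102), mode = "R0"))
    counts <- checkDot(dotText(r$doc))
    expect_equal(counts$nodes, 2)
    expect_equal(counts$edges, 1)
    # protein-protein: undirected black line
    expect_match(dotText(r$doc), 'color="black"')
    expect_match(dotText(r$doc), 'dir="none"')
    expect_match(dotText(r$doc), 'label="ABC"')
})

test_that("a gene is one hypernode regardless of its molecular roles", {
    # X has a PP edge to Y and an incoming PD arrow from Z: one node for X
    kb <- hKb(recs = list(hRec(1, 1, 2),
                          hRec(2, 3, 1, type = "protein_dna")),
              genes = list(hGene(1, symbol = "X"), hGene(2, symbol = "Y"),
                           hGene(3, symbol = "Z")))
    r <- renderAll(kb, querySpec(1))
    txt <- dotText(r$doc)
    expect_equal(length(gregexpr("\n  g1 \\[", txt)[[1]]), 1)
    counts <- checkDot(txt)
    expect_equal(counts$nodes, 3)
    expect_equal(counts$edges, 2)
    # the PD edge is a red arrow (no dir=none on it)
    pd <- regmatches(txt, regexpr("g3 -> g1 \\[[^]]*\\]", txt))
    expect_match(pd, 'color="red"')
    expect_false(grepl("dir=", pd))
})

test_that("stacks render as record nodes with per-member ports and URLs", {
    kb <- tinyKb()
    spec <- querySpec(NULL, groups = list(g = c(101L)))
    r <- renderAll(kb, spec)
    txt <- dotText(r$doc)
    counts <- checkDot(txt)
    expect_equal(counts$nodes,
                 length(stacks(r$partition)) + nrow(singletons(r$partition)))
    expect_match(txt, 'shape="record"')
    expect_match(txt, "<p101> TP53 \\[9606\\]\\|<p201> Trp53 \\[10090\\]")
    # per-member URL map entries reference the ports
    expect_true(all(c("hg7:p101", "hg7:p201") %in% names(urlMap(r$doc))))
})

test_that("every node and edge statement carries a mapped URL", {
    set.seed(77)
    kb <- generateFixture(50, 3, 120, seed = 77, userFraction = 0.2,
                          orthologFraction = 0.5)
    spec <- querySpec(sample(geneInfo(kb)$gene_id, 4))
    r <- renderAll(kb, spec)
    txt <- dotText(r$doc)
    counts <- checkDot(txt)
    expect_equal(counts$nodes,
                 length(stacks(r$partition)) + nrow(singletons(r$partition)))
    expect_equal(counts$edges, nrow(graphEdges(r$graph)))
    # URL totality: every mapped element's id occurs in the text
    for (id in names(urlMap(r$doc)))
        expect_true(grepl(id, txt, fixed = TRUE), label = id)
    # one URL per edge (by id attribute) and per node statement
    expect_equal(sum(startsWith(names(urlMap(r$doc)), "e")),
                 nrow(graphEdges(r$graph)))
    set.seed(NULL)
})

test_that("submitter attribution surfaces on user-submitted edges", {
    kb <- hKb(recs = list(hRec(1, 101, 102, submitter = "jdoe",
                               status = "user_submitted")),
              genes = list(hGene(101), hGene(102)))
    r <- renderAll(kb, querySpec(c(101, 102), mode = "R0"))
    expect_match(dotText(r$doc), "submitted by jdoe")
    expect_match(urlMap(r$doc)[["e1"]], "submitter=jdoe")
})

test_that("query groups color nodes and the legend lists them in order", {
    kb <- hKb(recs = list(hRec(1, 101, 102), hRec(2, 102, 103,
                                                  type = "protein_dna")),
              genes = list(hGene(101), hGene(102), hGene(103)))
    spec <- querySpec(NULL, mode = "R0",
                      groups = list(a = c(101L, 102L), b = c(102L, 103L)),
                      names = c("Up", "Down"))
    r <- renderAll(kb, spec)
    li <- legendItems(r$doc)
    # PP + PD encodings, then the two named groups: 4 items in fixed order
    expect_equal(nrow(li), 4)
    expect_equal(li$label, c("protein-protein interaction",
                             "protein->DNA interaction", "Up", "Down"))
    # multi-group node gets the first group's color and a marker
    n102 <- regmatches(dotText(r$doc),
                       regexpr("g102 \\[[^]]*\\]", dotText(r$doc)))
    expect_match(n102, '#0072B2')
    expect_match(n102, 'peripheries="2"')
})

test_that("legend items match the encodings actually present", {
    kb <- hKb(recs = list(hRec(1, 101, 102)),
              genes = list(hGene(101), hGene(102)))
    r <- renderAll(kb, querySpec(c(101, 102), mode = "R0"))
    expect_equal(nrow(legendItems(r$doc)), 1)  # PP only, single default group
    # brute-force count over a random fixture
    set.seed(88)
    kb <- generateFixture(40, 2, 120, seed = 88)
    spec <- querySpec(sample(geneInfo(kb)$gene_id, 5))
    r <- renderAll(kb, spec)
    present <- unique(graphEdges(r$graph)$interaction_type)
    expect_equal(nrow(legendItems(r$doc)), length(present))
    set.seed(NULL)
})

test_that("an empty graph still renders a valid document with a legend", {
    kb <- hKb(genes = list(hGene(101)))
    r <- renderAll(kb, querySpec(101))
    counts <- checkDot(dotText(r$doc))
    expect_equal(counts$nodes, 1)  # the isolated query gene
    expect_equal(counts$edges, 0)
    expect_equal(counts$subgraphs, 1)  # the legend cluster
})

test_that("identical inputs produce byte-identical DOT", {
    kb <- generateFixture(60, 3, 150, seed = 5, orthologFraction = 0.5)
    spec <- querySpec(geneInfo(kb)$gene_id[c(3, 9, 27)])
    d1 <- renderAll(kb, spec)$doc
    d2 <- renderAll(kb, spec)$doc
    expect_identical(dotText(d1), dotText(d2))
    expect_identical(urlMap(d1), urlMap(d2))
})

test_that("dot format writes verbatim; raster formats need the engine", {
    kb <- hKb(recs = list(hRec(1, 101, 102)),
              genes = list(hGene(101), hGene(102)))
    r <- renderAll(kb, querySpec(101))
    out <- withr::local_tempfile(fileext = ".dot")
    renderDot(r$doc, "dot", out)
    expect_identical(paste(readLines(out), collapse = "\n"),
                     dotText(r$doc))
    expect_match(dotText(r$doc), 'layout="sfdp"')  # layout hint in document
    if (Sys.which("sfdp") == "") {
        expect_error(renderDot(r$doc, "svg", withr::local_tempfile()),
                     "GraphViz", class = "netkb_environment_error")
    } else {
        svg <- withr::local_tempfile(fileext = ".svg")
        renderDot(r$doc, "svg", svg)
        expect_true(file.exists(svg))
    }
})

test_that("style configuration files override encodings and are validated", {
    cfg <- withr::local_tempfile()
    writeLines(c("# style", "edge_color.genetic=purple",
                 "group_color.1=#000000",
                 "record_url_template=https://kb.example/record/%s"), cfg)
    sc <- readStyleConfig(cfg)
    expect_equal(unname(sc$edgeColors["genetic"]), "purple")
    expect_equal(sc$groupPalette[1], "#000000")
    kb <- hKb(recs = list(hRec(1, 101, 102, type = "genetic")),
              genes = list(hGene(101), hGene(102)))
    spec <- querySpec(c(101, 102), mode = "R0")
    g <- extractSubgraph(spec, kb)
    doc <- toDot(g, buildPartition(g, kb, spec), spec, kb, sc)
    expect_match(dotText(doc), 'color="purple"')
    expect_match(urlMap(doc)[["e1"]], "kb.example/record/1")
    writeLines("edge_color.bogus=red", cfg)
    expect_error(readStyleConfig(cfg), "unknown interaction type",
                 class = "netkb_config_error")
})
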