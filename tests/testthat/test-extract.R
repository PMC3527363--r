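# The four radius modes against hand-worked examples and the brute-force
# oracles in helper-oracle.R.

test_that("radius 0 keeps only within-query interactions", {
    recs <- rbind(hRec(1, 1, 2), hRec(2, 1, 3))
    g <- extractR0(c(1, 2), recs)
    expect_equal(edgeRecordIds(g), 1)
    expect_equal(nodeIds(g), c(1, 2))  # 3 absent
    # disjoint query and records: query nodes survive as isolated nodes
    g <- extractR0(c(8, 9), recs)
    expect_equal(nrow(graphEdges(g)), 0)
    expect_equal(nodeIds(g), c(8, 9))
    expect_true(all(graphNodes(g)$role == "query"))
})

test_that("intermediates need two DISTINCT query neighbors", {
    # X touches A and B -> intermediate; Y touches only A -> excluded
    recs <- rbind(hRec(1, 1, 10), hRec(2, 2, 10), hRec(3, 1, 11))
    g <- extractR0Intermediates(c(1, 2), recs)
    expect_equal(nodeIds(g), c(1, 2, 10))
    expect_equal(edgeRecordIds(g), c(1, 2))
    expect_equal(graphNodes(g)$role[graphNodes(g)$gene_id == 10],
                 "intermediate")
    # two records to the SAME query gene do not make an intermediate
    recs <- rbind(hRec(1, 1, 10), hRec(2, 1, 10, type = "genetic"))
    g <- extractR0Intermediates(c(1, 2), recs)
    expect_equal(nodeIds(g), c(1, 2))
    expect_equal(nrow(graphEdges(g)), 0)
})

test_that("intermediate-intermediate edges are excluded", {
    recs <- rbind(hRec(1, 1, 10), hRec(2, 2, 10),
                  hRec(3, 1, 11), hRec(4, 2, 11),
                  hRec(5, 10, 11))  # between the two intermediates
    g <- extractR0Intermediates(c(1, 2), recs)
    expect_equal(edgeRecordIds(g), c(1, 2, 3, 4))
})

test_that("radius 1 is exactly the query-touching records", {
    # star: query at the hub
    recs <- do.call(rbind, lapply(1:5, function(i) hRec(i, 100, 100 + i)))
    g <- extractR1(100, recs)
    expect_equal(edgeRecordIds(g), 1:5)
    expect_equal(sum(graphNodes(g)$role == "neighbor"), 5)
    # path A-B-C, query the leaf: only A-B
    recs <- rbind(hRec(1, 1, 2), hRec(2, 2, 3))
    g <- extractR1(1, recs)
    expect_equal(edgeRecordIds(g), 1)
    expect_false(3 %in% nodeIds(g))
})

test_that("radius 2 reaches the neighbors' interactions but no further", {
    # path A-B-C-D, query A: A-B and B-C included, C-D not
    recs <- rbind(hRec(1, 1, 2), hRec(2, 2, 3), hRec(3, 3, 4))
    g <- extractR2(1, recs)
    expect_equal(edgeRecordIds(g), c(1, 2))
    roles <- setNames(graphNodes(g)$role, graphNodes(g)$gene_id)
    expect_equal(roles[["2"]], "neighbor")
    expect_equal(roles[["3"]], "second_shell")
    # triangle among three R1 neighbors: all neighbor-neighbor edges kept
    recs <- rbind(hRec(1, 1, 11), hRec(2, 1, 12), hRec(3, 1, 13),
                  hRec(4, 11, 12), hRec(5, 12, 13), hRec(6, 11, 13))
    g <- extractR2(1, recs)
    expect_equal(edgeRecordIds(g), 1:6)
})

test_that("direction is ignored for membership but kept on edges", {
    # a protein->DNA record pointing AT the query still yields a neighbor
    recs <- rbind(hRec(1, 10, 1, type = "protein_dna"))
    g <- extractR1(1, recs)
    expect_equal(nodeIds(g), c(1, 10))
    expect_true(graphEdges(g)$directed)
    expect_equal(graphEdges(g)$gene_a, 10)  # orientation preserved
})

test_that("all extractors agree with the brute-force oracle on random fixtures", {
    for (seed in 1:12) {
        set.seed(1000 + seed)
        kb <- generateFixture(sample(10:100, 1), 3, sample(20:250, 1),
                              seed = seed)
        recs <- interactions(kb)
        ids <- geneInfo(kb)$gene_id
        qs <- sample(ids, sample(2:6, 1))
        for (mode in c("R0", "R0_INTERMEDIATES", "R1", "R2")) {
            g <- switch(mode, R0 = extractR0(qs, recs),
                        R0_INTERMEDIATES = extractR0Intermediates(qs, recs),
                        R1 = extractR1(qs, recs), R2 = extractR2(qs, recs))
            o <- oracleExtract(mode, qs, recs)
            expect_equal(edgeRecordIds(g), o$records,
                         label = sprintf("records: seed %d %s", seed, mode))
            expect_equal(nodeIds(g), o$nodes,
                         label = sprintf("nodes: seed %d %s", seed, mode))
        }
    }
    set.seed(NULL)
})

test_that("edge sets nest across the four radius modes", {
    for (seed in 13:18) {
        set.seed(1000 + seed)
        kb <- generateFixture(60, 3, 180, seed = seed)
        recs <- interactions(kb)
        qs <- sample(geneInfo(kb)$gene_id, 4)
        r0 <- edgeRecordIds(extractR0(qs, recs))
        r0i <- edgeRecordIds(extractR0Intermediates(qs, recs))
        r1 <- edgeRecordIds(extractR1(qs, recs))
        r2 <- edgeRecordIds(extractR2(qs, recs))
        expect_true(all(r0 %in% r0i))
        expect_true(all(r0i %in% r1))
        expect_true(all(r1 %in% r2))
    }
    set.seed(NULL)
})

test_that("filters keep only the allowed types and statuses", {
    kb <- tinyKb()
    spec <- querySpec(c(101, 102, 103), mode = "R0",
                      types = "protein_protein")
    recs <- filterRecords(kb, spec)
    expect_true(all(recs$interaction_type == "protein_protein"))
    # shrinking include_types never adds records (monotone filter)
    specAll <- querySpec(c(101, 102, 103), mode = "R0")
    expect_true(all(recs$record_id %in%
                    filterRecords(kb, specAll)$record_id))
    # empty include set is a configuration error, not an empty graph
    # (slot assignment skips class validity, so filterRecords must check)
    specEmpty <- querySpec(101)
    specEmpty@includeTypes <- character(0)
    expect_error(filterRecords(kb, specEmpty),
                 class = "netkb_config_error")
})

test_that("single-organism mode drops cross-taxon records entirely", {
    kb <- hKb(recs = list(hRec(1, 101, 102),
                          hRec(2, 101, 201, taxB = 10090)),  # cross-taxon
              genes = list(hGene(101), hGene(102),
                           hGene(201, tax = 10090, symbol = "G201m")))
    spec <- querySpec(101, organism = 9606)
    recs <- filterRecords(kb, spec)
    expect_equal(recs$record_id, 1)
    g <- extractSubgraph(spec, kb)
    expect_true(all(graphNodes(g)$tax_id == 9606))
})

test_that("the effective query set expands orthologs and propagates groups", {
    kb <- tinyKb()
    # all-ortholog mode: 101 pulls in its mouse ortholog 201
    spec <- querySpec(NULL, groups = list(a = c(101L), b = c(102L, 101L)))
    qs <- effectiveQuerySet(spec, kb)
    expect_setequal(qs$gene_id, c(101, 201, 102, 202))
    expect_equal(qs$groups[[which(qs$gene_id == 201)]], c(1L, 2L))  # via 101
    expect_equal(qs$groups[[which(qs$gene_id == 102)]], 2L)
    # single-organism mode: no expansion, other-taxon members dropped
    spec <- querySpec(NULL, groups = list(a = c(101L, 201L)),
                      organism = 9606)
    expect_equal(effectiveQuerySet(spec, kb)$gene_id, 101)
    # oracle equivalence on random fixtures
    for (seed in c(21, 22)) {
        set.seed(1000 + seed)
        kb <- generateFixture(70, 3, 80, seed = seed, orthologFraction = 0.5)
        pick <- sample(geneInfo(kb)$gene_id, 5)
        spec <- querySpec(pick)
        expect_equal(sort(effectiveQuerySet(spec, kb)$gene_id),
                     oracleExpand(pick, kb))
    }
    set.seed(NULL)
})

test_that("duplicate documentation merges into one edge with all records", {
    kb <- hKb(recs = list(hRec(1, 101, 102, pubmed = "11111111"),
                          hRec(2, 102, 101, pubmed = "22222222"),
                          hRec(3, 101, 102, type = "genetic")),
              genes = list(hGene(101), hGene(102)))
    g <- extractSubgraph(querySpec(c(101, 102), mode = "R0"), kb)
    ed <- graphEdges(g)
    expect_equal(nrow(ed), 2)  # PP merged (either orientation), GI separate
    pp <- ed[ed$interaction_type == "protein_protein", ]
    expect_equal(pp$record_ids[[1]], c(1, 2))
    # directed records merge only in the same orientation
    kb2 <- hKb(recs = list(hRec(1, 101, 102, type = "protein_dna"),
                           hRec(2, 102, 101, type = "protein_dna")),
               genes = list(hGene(101), hGene(102)))
    g2 <- extractSubgraph(querySpec(c(101, 102), mode = "R0"), kb2)
    expect_equal(nrow(graphEdges(g2)), 2)
})

test_that("a query against an empty knowledgebase returns query nodes only", {
    kb <- hKb(genes = list(hGene(101), hGene(102)))
    g <- extractSubgraph(querySpec(c(101, 102), mode = "R1"), kb)
    expect_equal(nodeIds(g), c(101, 102))
    expect_equal(nrow(graphEdges(g)), 0)
})

test_that("graph serializes to JSON-lines with full record traceability", {
    kb <- tinyKb()
    g <- extractSubgraph(querySpec(101, mode = "R1"), kb)
    path <- withr::local_tempfile()
    writeEdgeList(g, path)
    lines <- readLines(path)
    expect_equal(length(lines), 1 + nrow(graphEdges(g)))
    header <- jsonlite::fromJSON(lines[1])
    expect_equal(header$type, "nodes")
    recIds <- unlist(lapply(lines[-1],
                            function(l) jsonlite::fromJSON(l)$record_ids))
    expect_setequal(recIds, unlist(graphEdges(g)$record_ids))
})
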