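prop <- function(a = 101, b = 103, type = "protein_protein",
                 pubmed = 33333333, submitter = "jdoe", taxA = 9606,
                 taxB = 9606) {
    interactionProposal(a, taxA, b, taxB, type, pubmed, submitter)
}

test_that("precheck flags duplicates and green-lights novelties", {
    kb <- tinyKb()
    # same unordered pair + type as record 1 -> warning, either orientation
    v <- precheckSubmission(prop(102, 101), kb)
    expect_equal(v$status, "redundant_warning")
    expect_equal(v$matches, 1)
    # messages echo resolved symbols and the submitted PubMed ids
    expect_match(paste(v$messages, collapse = "\n"), "MDM2")
    expect_match(paste(v$messages, collapse = "\n"), "TP53")
    expect_match(paste(v$messages, collapse = "\n"), "33333333")
    # same pair, different type: green light
    v <- precheckSubmission(prop(101, 102, type = "genetic"), kb)
    expect_equal(v$status, "green_light")
    expect_length(v$matches, 0)
})

test_that("direction matters for protein->DNA redundancy only", {
    kb <- tinyKb()  # record 2 is 101 ->(PD) 103
    expect_equal(precheckSubmission(prop(101, 103, "protein_dna"), kb)$status,
                 "redundant_warning")
    # reversed direction is a different regulatory claim
    expect_equal(precheckSubmission(prop(103, 101, "protein_dna"), kb)$status,
                 "green_light")
})

test_that("invalid proposals are reported, not thrown", {
    kb <- tinyKb()
    expect_equal(precheckSubmission(prop(pubmed = integer(0)), kb)$status,
                 "invalid")
    expect_equal(precheckSubmission(prop(pubmed = -5), kb)$status, "invalid")
    expect_equal(precheckSubmission(prop(submitter = " "), kb)$status,
                 "invalid")
    expect_equal(precheckSubmission(prop(type = "rna_rna"), kb)$status,
                 "invalid")
    # registry enforcement and taxon disagreement
    expect_equal(precheckSubmission(prop(), kb,
                                    registry = "other")$status, "invalid")
    expect_equal(precheckSubmission(prop(taxA = 10090), kb)$status,
                 "invalid")
    # precheck is read-only
    before <- interactions(kb)
    invisible(precheckSubmission(prop(), kb))
    expect_identical(interactions(kb), before)
})

test_that("commit appends an attributed record and a history event", {
    kb <- tinyKb()
    res <- commitSubmission(kb, prop(), timestamp = "2026-01-01T00:00:00Z")
    expect_equal(nrow(interactions(res$kb)), 5)
    expect_equal(nrow(historyLog(res$kb)), 1)
    rec <- interactions(res$kb)[interactions(res$kb)$record_id ==
                                res$recordId, ]
    expect_equal(rec$annotation_status, "user_submitted")
    expect_equal(rec$submitter, "jdoe")
    # redundant needs force; invalid is always rejected
    expect_error(commitSubmission(res$kb, prop()),
                 "redundant", class = "netkb_usage_error")
    expect_equal(nrow(interactions(commitSubmission(
        res$kb, prop(), force = TRUE,
        timestamp = "2026-01-01T00:00:01Z")$kb)), 6)
    expect_error(commitSubmission(kb, prop(pubmed = integer(0))),
                 "invalid", class = "netkb_usage_error")
})

test_that("commit then revert restores the serialization byte-for-byte", {
    kb <- tinyKb()
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeKnowledgebase(kb, d1)
    res <- commitSubmission(kb, prop(), timestamp = "2026-01-01T00:00:00Z")
    reverted <- revertTo(res$kb, 0)
    writeKnowledgebase(reverted, d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d2, f)),
                         readLines(file.path(d1, f)), label = f)
    # reverting to the latest state is the identity
    expect_identical(interactions(revertTo(res$kb,
        max(historyLog(res$kb)$sequence_no))), interactions(res$kb))
    expect_error(revertTo(res$kb, 99), "unknown",
                 class = "netkb_usage_error")
})

test_that("submitted records surface their submitter in query renderings", {
    kb <- tinyKb()
    res <- commitSubmission(kb, prop(104, 101, submitter = "asmith"),
                            timestamp = "2026-01-01T00:00:00Z")
    spec <- querySpec(101, organism = 9606)
    g <- extractSubgraph(spec, res$kb)
    doc <- toDot(g, buildPartition(g, res$kb, spec), spec, res$kb)
    expect_match(dotText(doc), "submitted by asmith")
})

test_that("random commit sequences replay to the identical table", {
    set.seed(55)
    kb <- generateFixture(40, 2, 80, seed = 55)
    ids <- geneInfo(kb)$gene_id
    committed <- kb
    n <- 0
    for (i in 1:50) {
        p <- interactionProposal(sample(ids, 1), 0, sample(ids, 1), 0,
            sample(c("protein_protein", "protein_dna", "genetic"), 1),
            sample.int(1e7, 1), sprintf("user%d", i %% 3))
        p$tax_a <- geneInfo(kb)$tax_id[match(p$gene_a, ids)]
        p$tax_b <- geneInfo(kb)$tax_id[match(p$gene_b, ids)]
        v <- precheckSubmission(p, committed)
        # verdict agrees with a brute-force duplicate scan
        ix <- interactions(committed)
        dup <- if (p$interaction_type == "protein_dna") {
            any(ix$interaction_type == p$interaction_type &
                ix$gene_a == p$gene_a & ix$gene_b == p$gene_b)
        } else {
            any(ix$interaction_type == p$interaction_type &
                ((ix$gene_a == p$gene_a & ix$gene_b == p$gene_b) |
                 (ix$gene_a == p$gene_b & ix$gene_b == p$gene_a)))
        }
        expect_equal(v$status == "redundant_warning", dup)
        if (v$status == "green_light") {
            committed <- commitSubmission(committed, p,
                timestamp = sprintf("2026-01-01T00:00:%02dZ", n))$kb
            n <- n + 1
        }
    }
    expect_gt(n, 10)
    # replaying the history over the curated baseline reproduces the table
    replayed <- replayHistory(committed)
    expect_identical(interactions(replayed), interactions(committed))
    # reverting to the midpoint equals replaying the first half
    mid <- floor(n / 2)
    reverted <- revertTo(committed, mid)
    half <- committed
    half@history <- historyLog(committed)[
        historyLog(committed)$sequence_no <= mid, ]
    expect_identical(interactions(reverted),
                     interactions(replayHistory(half)))
    set.seed(NULL)
})

test_that("a logged revert event replays correctly", {
    kb <- tinyKb()
    k1 <- commitSubmission(kb, prop(), timestamp = "t1")$kb
    k2 <- commitSubmission(k1, prop(103, 102, type = "protein_dna"),
                           timestamp = "t2")$kb
    k3 <- revertTo(k2, 1, log = TRUE, timestamp = "t3")
    expect_equal(historyLog(k3)$action, c("add", "add", "revert"))
    # replay must drop the record undone by the logged revert
    replayed <- replayHistory(k3, baseline = kb)
    expect_setequal(interactions(replayed)$record_id,
                    interactions(revertTo(k2, 1))$record_id)
})
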