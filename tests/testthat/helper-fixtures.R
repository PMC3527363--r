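# Hand-built knowledgebase fixtures for unit tests. These construct the
# S4 object directly so each test states its whole world in a few lines.

hGene <- function(id, tax = 9606L, symbol = paste0("G", id), synonyms = "",
                  description = "", go_terms = "") {
    data.frame(gene_id = as.integer(id), tax_id = as.integer(tax),
               symbol = symbol, synonyms = synonyms,
               description = description, go_terms = go_terms,
               stringsAsFactors = FALSE)
}

hRec <- function(id, a, b, type = "protein_protein", taxA = 9606L,
                 taxB = 9606L, pubmed = "11111111", submitter = "",
                 status = "curated") {
    data.frame(record_id = as.integer(id), gene_a = as.integer(a),
               tax_a = as.integer(taxA), gene_b = as.integer(b),
               tax_b = as.integer(taxB), interaction_type = type,
               directed = type == "protein_dna", pubmed_ids = pubmed,
               submitter = submitter, annotation_status = status,
               stringsAsFactors = FALSE)
}

hHom <- function(hid, ids, taxa) {
    data.frame(homologene_id = as.integer(hid), gene_id = as.integer(ids),
               tax_id = as.integer(taxa), stringsAsFactors = FALSE)
}

hKb <- function(recs = NULL, genes = NULL, hom = NULL) {
    args <- list("Knowledgebase")
    if (!is.null(recs)) args$interactions <- do.call(rbind, recs)
    if (!is.null(genes)) args$genes <- do.call(rbind, genes)
    if (!is.null(hom)) args$homology <- do.call(rbind, hom)
    do.call(methods::new, args)
}

# a small two-taxon world used across several test files:
# human TP53-like gene 101 with mouse ortholog 201 (group 7), human partners
# 102/103, a synonym collision on "p53b" between 102 and 103
tinyKb <- function() {
    hKb(
        recs = list(
            hRec(1, 101, 102),
            hRec(2, 101, 103, type = "protein_dna"),
            hRec(3, 201, 202, taxA = 10090, taxB = 10090),
            hRec(4, 102, 103, type = "genetic")),
        genes = list(
            hGene(101, symbol = "TP53", synonyms = "p53",
                  description = "tumor suppressor",
                  go_terms = "apoptosis|cell cycle"),
            hGene(102, symbol = "MDM2", synonyms = "p53b|HDM2",
                  description = "ubiquitin ligase", go_terms = "apoptosis"),
            hGene(103, symbol = "CDKN1A", synonyms = "p53b|p21",
                  description = "cell cycle inhibitor",
                  go_terms = "cell cycle"),
            hGene(201, tax = 10090, symbol = "Trp53", synonyms = "p53",
                  description = "tumor suppressor",
                  go_terms = "apoptosis"),
            hGene(202, tax = 10090, symbol = "Mdm2",
                  description = "ubiquitin ligase", go_terms = "")),
        hom = list(hHom(7, c(101, 201), c(9606, 10090)),
                   hHom(8, c(102, 202), c(9606, 10090))))
}

querySpec <- function(ids, mode = "R1", organism = NA_integer_,
                      types = c("protein_protein", "protein_dna", "genetic",
                                "other"),
                      statuses = c("curated", "user_submitted"),
                      groups = NULL, names = NULL) {
    if (is.null(groups)) groups <- list(as.integer(ids))
    if (is.null(names)) names <- sprintf("Query Group %d", seq_along(groups))
    names(groups) <- names
    methods::new("QuerySpec", groups = lapply(groups, as.integer),
                 radiusMode = mode, organism = as.integer(organism),
                 includeTypes = types, includeStatus = statuses)
}

# sorted record ids over all merged edges / sorted node ids
edgeRecordIds <- function(g) {
    r <- unlist(graphEdges(g)$record_ids)
    if (is.null(r)) integer(0) else sort(r)
}
nodeIds <- function(g) sort(graphNodes(g)$gene_id)
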