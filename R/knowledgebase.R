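## On-disk TSV dialect. One header row each; all files tab-separated, never
## quoted (fields may not contain tabs or newlines):
##   interactions.tsv: record_id, gene_a, tax_a, gene_b, tax_b,
##     interaction_type {PP|PD|GI|OTHER}, direction {AB|NONE},
##     pubmed_ids (comma-joined), submitter ("" = curated import),
##     status {curated|user}
##   gene_info.tsv: gene_id, tax_id, symbol, synonyms (pipe-joined),
##     description, go_terms (pipe-joined)
##   homologene.tsv: homologene_id, gene_id, tax_id (one row per member)
##   history.tsv: sequence_no, action, record_id, user, timestamp

INTERACTIONS_COLS <- c("record_id", "gene_a", "tax_a", "gene_b", "tax_b",
                       "interaction_type", "direction", "pubmed_ids",
                       "submitter", "status")
GENEINFO_COLS <- c("gene_id", "tax_id", "symbol", "synonyms", "description",
                   "go_terms")
HOMOLOGY_COLS <- c("homologene_id", "gene_id", "tax_id")
HISTORY_COLS <- c("sequence_no", "action", "record_id", "user", "timestamp")

readTsv <- function(path, cols) {
    if (!file.exists(path))
        nkbStop("netkb_parse_error", "file not found: %s", path)
    df <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE, quote = "",
                            check.names = FALSE)
    if (!identical(names(df), cols))
        nkbStop("netkb_parse_error",
                "%s: expected columns [%s], found [%s]", path,
                paste(cols, collapse = ", "), paste(names(df), collapse = ", "))
    df
}

## convert a character column to integer, reporting 1-based data line numbers
## (line 1 = first row after the header) for anything non-integer
asIntCol <- function(x, col, path) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(is.na(out))
    if (length(bad))
        nkbStop("netkb_parse_error", "%s: non-integer %s on line %s",
                path, col, paste(bad, collapse = ", "))
    out
}

enumCol <- function(x, allowed, col, path) {
    bad <- which(!(x %in% allowed))
    if (length(bad))
        nkbStop("netkb_parse_error",
                "%s: invalid %s (%s) on line %s; allowed: %s", path, col,
                paste(unique(x[bad]), collapse = ", "),
                paste(bad, collapse = ", "), paste(allowed, collapse = "|"))
    x
}

#' Load a knowledgebase from its TSV tables
#'
#' Reads the interaction, gene-annotation and ortholog-group tables (plus an
#' optional change-history table) in the documented tab-separated dialect,
#' validates every record-level invariant (non-empty PubMed support,
#' direction consistent with interaction type, submitter present on user
#' submissions, unique identifiers) and returns a validated
#' [Knowledgebase-class] object.
#'
#' Malformed rows raise a parse error naming the offending data line
#' (1-based, excluding the header); duplicated record identifiers raise an
#' integrity error. Genes referenced by interactions but absent from the
#' gene table are tolerated with a warning.
#'
#' @param interactionsPath path to interactions.tsv
#' @param geneInfoPath path to gene_info.tsv
#' @param homologyPath path to homologene.tsv
#' @param historyPath optional path to history.tsv (missing file = empty
#'   history)
#' @return a [Knowledgebase-class]
#' @examples
#' dir <- tempfile(); kb0 <- generateFixture(10, 2, 12, seed = 1)
#' writeKnowledgebase(kb0, dir)
#' kb <- loadKnowledgebase(file.path(dir, "interactions.tsv"),
#'                         file.path(dir, "gene_info.tsv"),
#'                         file.path(dir, "homologene.tsv"))
#' kb
#' @export
loadKnowledgebase <- function(interactionsPath, geneInfoPath, homologyPath,
                              historyPath = NULL) {
    raw <- readTsv(interactionsPath, INTERACTIONS_COLS)
    ix <- data.frame(
        record_id = asIntCol(raw$record_id, "record_id", interactionsPath),
        gene_a = asIntCol(raw$gene_a, "gene_a", interactionsPath),
        tax_a = asIntCol(raw$tax_a, "tax_a", interactionsPath),
        gene_b = asIntCol(raw$gene_b, "gene_b", interactionsPath),
        tax_b = asIntCol(raw$tax_b, "tax_b", interactionsPath),
        interaction_type = names(TYPE_CODES)[match(
            enumCol(raw$interaction_type, TYPE_CODES, "interaction_type",
                    interactionsPath), TYPE_CODES)],
        directed = enumCol(raw$direction, c("AB", "NONE"), "direction",
                           interactionsPath) == "AB",
        pubmed_ids = raw$pubmed_ids,
        submitter = raw$submitter,
        annotation_status = names(STATUS_CODES)[match(
            enumCol(raw$status, STATUS_CODES, "status", interactionsPath),
            STATUS_CODES)],
        stringsAsFactors = FALSE)
    badPm <- which(!vapply(strsplit(ix$pubmed_ids, ","), function(p) {
        p <- suppressWarnings(as.integer(p))
        length(p) > 0 && !anyNA(p) && all(p > 0)
    }, logical(1)))
    if (length(badPm))
        nkbStop("netkb_parse_error", "%s: empty or malformed pubmed_ids on line %s",
                interactionsPath, paste(badPm, collapse = ", "))
    if (anyDuplicated(ix$record_id))
        nkbStop("netkb_integrity_error", "%s: duplicate record_id(s): %s",
                interactionsPath,
                paste(unique(ix$record_id[duplicated(ix$record_id)]),
                      collapse = ", "))

    raw <- readTsv(geneInfoPath, GENEINFO_COLS)
    gn <- data.frame(
        gene_id = asIntCol(raw$gene_id, "gene_id", geneInfoPath),
        tax_id = asIntCol(raw$tax_id, "tax_id", geneInfoPath),
        symbol = raw$symbol, synonyms = raw$synonyms,
        description = raw$description, go_terms = raw$go_terms,
        stringsAsFactors = FALSE)

    raw <- readTsv(homologyPath, HOMOLOGY_COLS)
    hm <- data.frame(
        homologene_id = asIntCol(raw$homologene_id, "homologene_id", homologyPath),
        gene_id = asIntCol(raw$gene_id, "gene_id", homologyPath),
        tax_id = asIntCol(raw$tax_id, "tax_id", homologyPath),
        stringsAsFactors = FALSE)

    hs <- emptyHistory()
    if (!is.null(historyPath) && file.exists(historyPath)) {
        raw <- readTsv(historyPath, HISTORY_COLS)
        hs <- data.frame(
            sequence_no = asIntCol(raw$sequence_no, "sequence_no", historyPath),
            action = enumCol(raw$action, c("add", "revert"), "action",
                             historyPath),
            record_id = asIntCol(raw$record_id, "record_id", historyPath),
            user = raw$user, timestamp = raw$timestamp,
            stringsAsFactors = FALSE)
    }

    kb <- methods::new("Knowledgebase", interactions = ix, genes = gn,
                       homology = hm, history = hs)
    orphan <- setdiff(unique(c(ix$gene_a, ix$gene_b)), gn$gene_id)
    if (length(orphan))
        warning(sprintf("%d interacting gene(s) absent from gene_info; labeled by raw id: %s",
                        length(orphan),
                        paste(utils::head(orphan, 10), collapse = ", ")),
                call. = FALSE)
    methods::validObject(kb)
    kb
}

canonicalizeKb <- function(kb) {
    kb@interactions <- kb@interactions[order(kb@interactions$record_id), ,
                                       drop = FALSE]
    kb@genes <- kb@genes[order(kb@genes$gene_id), , drop = FALSE]
    kb@homology <- kb@homology[order(kb@homology$homologene_id,
                                     kb@homology$gene_id), , drop = FALSE]
    kb@history <- kb@history[order(kb@history$sequence_no), , drop = FALSE]
    rownames(kb@interactions) <- rownames(kb@genes) <- NULL
    rownames(kb@homology) <- rownames(kb@history) <- NULL
    kb
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "")
    path
}

#' Write a knowledgebase to canonical TSV tables
#'
#' Serializes all four tables into `dir` in a canonical, deterministically
#' sorted form (interactions by record_id, genes by gene_id, homology by
#' group then gene, history by sequence number), so that
#' `loadKnowledgebase()` after `writeKnowledgebase()` is the identity and
#' repeated writes of the same object are byte-identical.
#'
#' @param kb a [Knowledgebase-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the named character vector of the four file paths
#' @export
writeKnowledgebase <- function(kb, dir) {
    methods::validObject(kb)
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        nkbStop("netkb_config_error", "cannot create directory: %s", dir)
    kb <- canonicalizeKb(kb)
    ix <- kb@interactions
    out <- data.frame(
        record_id = ix$record_id, gene_a = ix$gene_a, tax_a = ix$tax_a,
        gene_b = ix$gene_b, tax_b = ix$tax_b,
        interaction_type = TYPE_CODES[ix$interaction_type],
        direction = ifelse(ix$directed, "AB", "NONE"),
        pubmed_ids = ix$pubmed_ids, submitter = ix$submitter,
        status = STATUS_CODES[ix$annotation_status],
        stringsAsFactors = FALSE)
    paths <- c(
        interactions = writeTsv(out, file.path(dir, "interactions.tsv")),
        gene_info = writeTsv(kb@genes, file.path(dir, "gene_info.tsv")),
        homologene = writeTsv(kb@homology, file.path(dir, "homologene.tsv")),
        history = writeTsv(kb@history, file.path(dir, "history.tsv")))
    invisible(paths)
}

#' Load a knowledgebase from a directory written by writeKnowledgebase
#'
#' @param dir directory containing interactions.tsv, gene_info.tsv,
#'   homologene.tsv and optionally history.tsv
#' @return a [Knowledgebase-class]
#' @export
loadKnowledgebaseDir <- function(dir) {
    loadKnowledgebase(file.path(dir, "interactions.tsv"),
                      file.path(dir, "gene_info.tsv"),
                      file.path(dir, "homologene.tsv"),
                      file.path(dir, "history.tsv"))
}
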