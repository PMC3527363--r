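#' @import methods
NULL

## Enumerations used across the package. Interaction types follow the
## hypernode convention: the molecular role of a gene (DNA vs protein) is
## implied by each incident edge's type, never by node duplication.
INTERACTION_TYPES <- c("protein_protein", "protein_dna", "genetic", "other")
ANNOTATION_STATUSES <- c("curated", "user_submitted")
RADIUS_MODES <- c("R0", "R0_INTERMEDIATES", "R1", "R2")
NODE_ROLES <- c("query", "intermediate", "neighbor", "second_shell")

## TSV dialect codes <-> internal enum values
TYPE_CODES <- c(protein_protein = "PP", protein_dna = "PD",
                genetic = "GI", other = "OTHER")
STATUS_CODES <- c(curated = "curated", user_submitted = "user")

emptyInteractions <- function() {
    data.frame(record_id = integer(0), gene_a = integer(0), tax_a = integer(0),
               gene_b = integer(0), tax_b = integer(0),
               interaction_type = character(0), directed = logical(0),
               pubmed_ids = character(0), submitter = character(0),
               annotation_status = character(0), stringsAsFactors = FALSE)
}

emptyGeneInfo <- function() {
    data.frame(gene_id = integer(0), tax_id = integer(0),
               symbol = character(0), synonyms = character(0),
               description = character(0), go_terms = character(0),
               stringsAsFactors = FALSE)
}

emptyHomology <- function() {
    data.frame(homologene_id = integer(0), gene_id = integer(0),
               tax_id = integer(0), stringsAsFactors = FALSE)
}

emptyHistory <- function() {
    data.frame(sequence_no = integer(0), action = character(0),
               record_id = integer(0), user = character(0),
               timestamp = character(0), stringsAsFactors = FALSE)
}

#' Knowledgebase of documented biomolecular interactions
#'
#' In-memory representation of the four on-disk tables: the interaction
#' table (one row per documented interaction, each backed by one or more
#' PubMed identifiers), the gene-annotation table (taxon, official symbol,
#' synonyms, description, GO terms), the ortholog-group table (one row per
#' group member, HomoloGene-style), and the append-only change history for
#' user submissions.
#'
#' Interactions reference genes by positive Entrez-style integer identifiers
#' that are unique across taxa. Genes referenced by interactions but absent
#' from the annotation table are tolerated (real interaction corpora contain
#' such orphans) and labeled by raw identifier in rendered output.
#'
#' @slot interactions data.frame with columns record_id, gene_a, tax_a,
#'   gene_b, tax_b, interaction_type, directed, pubmed_ids (comma-joined),
#'   submitter, annotation_status.
#' @slot genes data.frame with columns gene_id, tax_id, symbol, synonyms
#'   (pipe-joined), description, go_terms (pipe-joined).
#' @slot homology data.frame with columns homologene_id, gene_id, tax_id.
#' @slot history data.frame with columns sequence_no, action, record_id,
#'   user, timestamp.
#'
#' @seealso [loadKnowledgebase()], [writeKnowledgebase()], [generateFixture()]
#' @export
setClass("Knowledgebase",
    representation(interactions = "data.frame", genes = "data.frame",
                   homology = "data.frame", history = "data.frame"),
    prototype(interactions = emptyInteractions(), genes = emptyGeneInfo(),
              homology = emptyHomology(), history = emptyHistory()))

validateInteractions <- function(ix) {
    msgs <- character(0)
    bad <- function(cond, fmt) {
        rows <- which(cond)
        if (length(rows))
            sprintf(fmt, paste(rows, collapse = ", "))
        else
            character(0)
    }
    if (anyDuplicated(ix$record_id))
        msgs <- c(msgs, sprintf("duplicate record_id(s): %s",
            paste(unique(ix$record_id[duplicated(ix$record_id)]), collapse = ", ")))
    msgs <- c(msgs,
        bad(!(ix$interaction_type %in% INTERACTION_TYPES),
            "unknown interaction_type in row(s) %s"),
        bad(!(ix$annotation_status %in% ANNOTATION_STATUSES),
            "unknown annotation_status in row(s) %s"),
        bad(ix$gene_a <= 0 | ix$gene_b <= 0 | ix$tax_a <= 0 | ix$tax_b <= 0,
            "non-positive gene or taxon id in row(s) %s"),
        ## every interaction must cite literature
        bad(!vapply(strsplit(ix$pubmed_ids, ","), function(p) {
                p <- suppressWarnings(as.integer(p))
                length(p) > 0 && !anyNA(p) && all(p > 0)
            }, logical(1)),
            "empty or malformed pubmed_ids in row(s) %s"),
        ## direction is a property of the type: protein->DNA is the only
        ## directed kind (regulator -> target)
        bad(ix$directed != (ix$interaction_type == "protein_dna"),
            "direction inconsistent with interaction_type in row(s) %s"),
        bad(ix$annotation_status == "user_submitted" & !nzchar(ix$submitter),
            "user_submitted record without submitter in row(s) %s"))
    msgs
}

setValidity("Knowledgebase", function(object) {
    ix <- object@interactions
    gn <- object@genes
    hm <- object@homology
    msgs <- validateInteractions(ix)
    if (anyDuplicated(gn$gene_id))
        msgs <- c(msgs, "duplicate gene_id in gene table")
    ## official symbols unique within a taxon (case-insensitive); synonyms
    ## may collide -- ambiguity is resolved at query time instead
    key <- paste(gn$tax_id, tolower(gn$symbol))
    if (anyDuplicated(key))
        msgs <- c(msgs, "official symbol duplicated within a taxon")
    if (anyDuplicated(hm$gene_id))
        msgs <- c(msgs, "a gene_id belongs to more than one homology group")
    ## taxon of a gene reference must agree with the gene table where known
    taxOf <- stats::setNames(gn$tax_id, gn$gene_id)
    chk <- function(g, t) {
        known <- as.character(g) %in% names(taxOf)
        any(known & taxOf[as.character(g)] != t)
    }
    if (nrow(ix) && (chk(ix$gene_a, ix$tax_a) || chk(ix$gene_b, ix$tax_b)))
        msgs <- c(msgs, "interaction endpoint taxon disagrees with gene table")
    if (nrow(hm) && chk(hm$gene_id, hm$tax_id))
        msgs <- c(msgs, "homology member taxon disagrees with gene table")
    hs <- object@history
    if (nrow(hs) && any(diff(hs$sequence_no) <= 0))
        msgs <- c(msgs, "history sequence_no not strictly increasing")
    if (length(msgs)) msgs else TRUE
})

#' Parsed multi-group query specification
#'
#' A validated user request: up to three named query groups of resolved gene
#' identifiers, a network-radius mode, an optional single-organism
#' constraint (absent means all-ortholog mode, the default behavior), and
#' interaction-type / annotation-status filters. A gene may appear in more
#' than one group; color precedence across groups is decided at render time.
#'
#' @slot groups named list (length 1-3) of integer gene_id vectors.
#' @slot radiusMode one of "R0", "R0_INTERMEDIATES", "R1", "R2".
#' @slot organism integer taxon id, or NA for all-ortholog mode.
#' @slot includeTypes subset of the interaction-type enumeration.
#' @slot includeStatus subset of the annotation-status enumeration.
#'
#' @seealso [parseQuery()], [extractSubgraph()]
#' @export
setClass("QuerySpec",
    representation(groups = "list", radiusMode = "character",
                   organism = "integer", includeTypes = "character",
                   includeStatus = "character"),
    prototype(groups = list(), radiusMode = "R1", organism = NA_integer_,
              includeTypes = INTERACTION_TYPES,
              includeStatus = ANNOTATION_STATUSES))

setValidity("QuerySpec", function(object) {
    msgs <- character(0)
    g <- object@groups
    if (length(g) < 1L || length(g) > 3L)
        msgs <- c(msgs, "between 1 and 3 query groups required")
    if (is.null(names(g)) || any(!nzchar(names(g))))
        msgs <- c(msgs, "every query group must be named")
    if (any(vapply(g, length, 1L) == 0L))
        msgs <- c(msgs, "empty query group")
    if (!(object@radiusMode %in% RADIUS_MODES))
        msgs <- c(msgs, "unknown radius mode")
    if (length(object@includeTypes) == 0L ||
        !all(object@includeTypes %in% INTERACTION_TYPES))
        msgs <- c(msgs, "includeTypes must be a non-empty subset of the interaction types")
    if (length(object@includeStatus) == 0L ||
        !all(object@includeStatus %in% ANNOTATION_STATUSES))
        msgs <- c(msgs, "includeStatus must be a non-empty subset of the annotation statuses")
    if (length(msgs)) msgs else TRUE
})

#' Result graph of a network-radius query
#'
#' A hypernode graph: one node per gene regardless of molecular role, typed
#' multi-edges merged by (unordered pair, type, direction) with the
#' underlying record identifiers retained for traceability, per-node roles
#' under the radius mode, and query-group membership.
#'
#' @slot nodes data.frame with columns gene_id, tax_id, role.
#' @slot edges data.frame with columns gene_a, tax_a, gene_b, tax_b,
#'   interaction_type, directed, and list-column record_ids.
#' @slot queryMembership named list: gene_id -> integer vector of group
#'   indices (1-based).
#' @slot groupNames character vector of query-group names.
#'
#' @seealso [extractSubgraph()], [buildPartition()], [toDot()]
#' @export
setClass("InteractionGraph",
    representation(nodes = "data.frame", edges = "data.frame",
                   queryMembership = "list", groupNames = "character"),
    prototype(nodes = data.frame(gene_id = integer(0), tax_id = integer(0),
                                 role = character(0), stringsAsFactors = FALSE),
              edges = data.frame(), queryMembership = list(),
              groupNames = character(0)))

setValidity("InteractionGraph", function(object) {
    nd <- object@nodes
    ed <- object@edges
    msgs <- character(0)
    if (!all(nd$role %in% NODE_ROLES))
        msgs <- c(msgs, "unknown node role")
    if (nrow(ed)) {
        if (!all(c(ed$gene_a, ed$gene_b) %in% nd$gene_id))
            msgs <- c(msgs, "edge endpoint missing from node table")
        if (any(vapply(ed$record_ids, length, 1L) == 0L))
            msgs <- c(msgs, "edge without traceable record_ids")
    }
    ## no isolated non-query nodes: every non-query node carries >= 1 edge
    touched <- unique(c(ed$gene_a, ed$gene_b))
    if (any(nd$role != "query" & !(nd$gene_id %in% touched)))
        msgs <- c(msgs, "isolated non-query node")
    if (length(msgs)) msgs else TRUE
})

#' Ortholog compound-node partition of a result graph
#'
#' Nodes sharing an ortholog group are drawn as one stacked (compound) node
#' only when each member has at least one interaction that appears in the
#' drawn graph; all other nodes are singletons. Stacks and singletons
#' together partition the graph's node set.
#'
#' @slot stacks list of lists, each with elements homologene_id and a
#'   members data.frame (gene_id, tax_id) ordered by tax_id.
#' @slot singletons data.frame (gene_id, tax_id).
#'
#' @seealso [buildPartition()]
#' @export
setClass("CompoundPartition",
    representation(stacks = "list", singletons = "data.frame"),
    prototype(stacks = list(),
              singletons = data.frame(gene_id = integer(0),
                                      tax_id = integer(0))))

#' Rendered DOT document
#'
#' GraphViz DOT text for a result graph plus the element -> URL map used for
#' clickable output and the auto-generated legend entries.
#'
#' @slot dotText single character string in the DOT grammar.
#' @slot urlMap named character vector: DOT element id -> URL.
#' @slot legendItems data.frame with columns glyph and label.
#'
#' @seealso [toDot()], [renderDot()]
#' @export
setClass("DotDocument",
    representation(dotText = "character", urlMap = "character",
                   legendItems = "data.frame"),
    prototype(dotText = "", urlMap = character(0),
              legendItems = data.frame(glyph = character(0),
                                       label = character(0))))
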