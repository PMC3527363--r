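## Network-radius subgraph extraction. Radius here is the prescribed graph
## distance with respect to the query genes, not the graph-theoretic radius:
##   R0               only interactions between query-list members
##   R0_INTERMEDIATES R0 plus non-query genes interacting with >= 2 distinct
##                    query members, and their query-side edges only
##   R1               every interaction touching a query member
##   R2               R1 plus every interaction touching an R1 interactant
## Direction is ignored for neighborhood membership (a protein->DNA target
## of a query gene is a neighbor) but preserved on edges.

#' Effective query set of a QuerySpec
#'
#' The union of all group members, expanded across ortholog groups when the
#' spec has no single-organism constraint (the default, all-ortholog
#' behavior) and restricted to the constraint taxon otherwise. Orthologs
#' inherit the query-group memberships of the gene that pulled them in; a
#' gene pulled in by several groups carries all of them.
#'
#' @param spec a [QuerySpec-class]
#' @param kb a [Knowledgebase-class]
#' @return data.frame with columns gene_id, tax_id and list-column `groups`
#'   (sorted integer group indices), ordered by (tax_id, gene_id)
#' @export
effectiveQuerySet <- function(spec, kb) {
    methods::validObject(spec)
    memb <- list()  # gene_id (chr) -> integer group indices
    addMember <- function(gid, grp) {
        key <- as.character(gid)
        memb[[key]] <<- sort(unique(c(memb[[key]], grp)))
    }
    singleOrg <- !is.na(spec@organism)
    for (gi in seq_along(spec@groups)) {
        for (g in spec@groups[[gi]]) {
            if (singleOrg) {
                if (isTRUE(taxOf(g, kb) == spec@organism))
                    addMember(g, gi)
            } else {
                ex <- expandOrthologs(g, kb)[[1]]
                for (m in ex$gene_id) addMember(m, gi)
            }
        }
    }
    ids <- as.integer(names(memb))
    tax <- taxOf(ids, kb)
    ## orphan query genes (absent from gene_info): take the taxon recorded
    ## on any interaction that references them
    for (i in which(is.na(tax))) {
        ix <- kb@interactions
        hit <- c(ix$tax_a[ix$gene_a == ids[i]], ix$tax_b[ix$gene_b == ids[i]])
        if (length(hit)) tax[i] <- hit[1]
    }
    df <- data.frame(gene_id = ids, tax_id = tax)
    df$groups <- I(unname(memb))
    df <- df[order(df$tax_id, df$gene_id), , drop = FALSE]
    rownames(df) <- NULL
    df
}

#' Filter interaction records by a QuerySpec
#'
#' Keeps records whose interaction type and annotation status are in the
#' spec's include sets. Under a single-organism constraint only records with
#' BOTH endpoints in that taxon survive, so cross-taxon records never leak
#' into single-species drawings.
#'
#' @param kb a [Knowledgebase-class]
#' @param spec a [QuerySpec-class]
#' @return interactions data.frame subset
#' @export
filterRecords <- function(kb, spec) {
    if (length(spec@includeTypes) == 0)
        nkbStop("netkb_config_error",
                "includeTypes is empty; every query would return an empty graph")
    ix <- kb@interactions
    keep <- ix$interaction_type %in% spec@includeTypes &
        ix$annotation_status %in% spec@includeStatus
    if (!is.na(spec@organism))
        keep <- keep & ix$tax_a == spec@organism & ix$tax_b == spec@organism
    out <- ix[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}

## shared assembly: record-level selection + roles -> InteractionGraph with
## merged, deterministically ordered edges
buildGraph <- function(querySet, records, keep, roles,
                       groupNames = character(0)) {
    qs <- querySet$gene_id
    sel <- records[keep, , drop = FALSE]
    ## node table: query genes always retained (even isolated, so the user
    ## sees a queried gene with no results), plus selected endpoints
    ndId <- c(qs, sel$gene_a, sel$gene_b)
    ndTax <- c(querySet$tax_id, sel$tax_a, sel$tax_b)
    dup <- duplicated(ndId)
    nodes <- data.frame(gene_id = ndId[!dup], tax_id = ndTax[!dup])
    nodes$role <- ifelse(nodes$gene_id %in% qs, "query",
                         roles[as.character(nodes$gene_id)])
    nodes <- nodes[order(nodes$tax_id, nodes$gene_id), , drop = FALSE]
    rownames(nodes) <- NULL

    ## merge duplicate documentation: same unordered pair + type (+ ordered
    ## pair for directed types) becomes one edge carrying all record ids
    if (nrow(sel)) {
        flip <- !sel$directed & sel$gene_a > sel$gene_b
        ga <- ifelse(flip, sel$gene_b, sel$gene_a)
        ta <- ifelse(flip, sel$tax_b, sel$tax_a)
        gb <- ifelse(flip, sel$gene_a, sel$gene_b)
        tb <- ifelse(flip, sel$tax_a, sel$tax_b)
        key <- paste(ga, gb, sel$interaction_type, sel$directed)
        first <- !duplicated(key)
        edges <- data.frame(gene_a = ga[first], tax_a = ta[first],
                            gene_b = gb[first], tax_b = tb[first],
                            interaction_type = sel$interaction_type[first],
                            directed = sel$directed[first],
                            stringsAsFactors = FALSE)
        edges$record_ids <- I(unname(lapply(split(sel$record_id, key)[key[first]],
                                            function(r) sort(r))))
        ord <- order(edges$tax_a, edges$gene_a, edges$tax_b, edges$gene_b,
                     match(edges$interaction_type, INTERACTION_TYPES))
        edges <- edges[ord, , drop = FALSE]
        rownames(edges) <- NULL
    } else {
        edges <- data.frame(gene_a = integer(0), tax_a = integer(0),
                            gene_b = integer(0), tax_b = integer(0),
                            interaction_type = character(0),
                            directed = logical(0))
        edges$record_ids <- I(list())
    }
    qm <- querySet$groups
    names(qm) <- as.character(querySet$gene_id)
    methods::new("InteractionGraph", nodes = nodes, edges = edges,
                 queryMembership = lapply(qm, as.integer),
                 groupNames = groupNames)
}

normalizeQuerySet <- function(querySet) {
    if (is.data.frame(querySet)) {
        if (is.null(querySet$groups))
            querySet$groups <- I(rep(list(1L), nrow(querySet)))
        querySet
    } else {
        data.frame(gene_id = as.integer(querySet),
                   tax_id = rep(NA_integer_, length(querySet)),
                   groups = I(rep(list(1L), length(querySet))))
    }
}

#' Radius-0 extraction: interactions within the query list
#'
#' Edges are exactly the records with both endpoints in the query set.
#' Query members are retained as nodes even when isolated.
#'
#' @param querySet data.frame (gene_id, tax_id, optional list-column groups)
#'   as returned by [effectiveQuerySet()], or a plain integer vector of gene
#'   ids
#' @param records interactions data.frame (typically [filterRecords()] output)
#' @return an [InteractionGraph-class]
#' @export
extractR0 <- function(querySet, records) {
    querySet <- normalizeQuerySet(querySet)
    qs <- querySet$gene_id
    keep <- records$gene_a %in% qs & records$gene_b %in% qs
    buildGraph(querySet, records, keep, character(0))
}

#' Radius-0-with-intermediates extraction
#'
#' All radius-0 edges, plus every non-query gene whose distinct query-member
#' neighbors (over the surviving records, ignoring direction) number at
#' least two — an "intermediate" — together with each of its edges to query
#' members. Two records linking a gene to the same single query member do
#' not make it an intermediate, and intermediate-intermediate edges are not
#' included.
#'
#' @inheritParams extractR0
#' @return an [InteractionGraph-class]
#' @export
extractR0Intermediates <- function(querySet, records) {
    querySet <- normalizeQuerySet(querySet)
    qs <- querySet$gene_id
    aIn <- records$gene_a %in% qs
    bIn <- records$gene_b %in% qs
    r0 <- aIn & bIn
    ## candidate crossing edges: exactly one endpoint queried
    cross <- xor(aIn, bIn)
    outside <- ifelse(aIn, records$gene_b, records$gene_a)[cross]
    queried <- ifelse(aIn, records$gene_a, records$gene_b)[cross]
    nDistinct <- vapply(split(queried, outside),
                        function(q) length(unique(q)), 1L)
    inter <- as.integer(names(nDistinct)[nDistinct >= 2L])
    keep <- r0
    keep[which(cross)[outside %in% inter]] <- TRUE
    roles <- stats::setNames(rep("intermediate", length(inter)),
                             as.character(inter))
    buildGraph(querySet, records, keep, roles)
}

#' Radius-1 extraction: all interactions touching the query list
#'
#' Edges are exactly the records with at least one endpoint in the query
#' set; non-query endpoints become neighbors.
#'
#' @inheritParams extractR0
#' @return an [InteractionGraph-class]
#' @export
extractR1 <- function(querySet, records) {
    querySet <- normalizeQuerySet(querySet)
    qs <- querySet$gene_id
    keep <- records$gene_a %in% qs | records$gene_b %in% qs
    roles <- character(0)
    if (any(keep)) {
        n1 <- setdiff(unique(c(records$gene_a[keep], records$gene_b[keep])), qs)
        roles <- stats::setNames(rep("neighbor", length(n1)),
                                 as.character(n1))
    }
    buildGraph(querySet, records, keep, roles)
}

#' Radius-2 extraction: radius-1 plus the neighbors' interactions
#'
#' All radius-1 edges plus every record touching a radius-1 interactant;
#' this includes neighbor-neighbor edges. Endpoints beyond the first shell
#' get role second_shell.
#'
#' @inheritParams extractR0
#' @return an [InteractionGraph-class]
#' @export
extractR2 <- function(querySet, records) {
    querySet <- normalizeQuerySet(querySet)
    qs <- querySet$gene_id
    r1 <- records$gene_a %in% qs | records$gene_b %in% qs
    n1 <- setdiff(unique(c(records$gene_a[r1], records$gene_b[r1])), qs)
    keep <- r1 | records$gene_a %in% n1 | records$gene_b %in% n1
    shell2 <- setdiff(unique(c(records$gene_a[keep], records$gene_b[keep])),
                      c(qs, n1))
    roles <- stats::setNames(
        c(rep("neighbor", length(n1)), rep("second_shell", length(shell2))),
        as.character(c(n1, shell2)))
    buildGraph(querySet, records, keep, roles)
}

#' Run a full query: resolve, filter, extract
#'
#' Composes [effectiveQuerySet()], [filterRecords()] and the radius-mode
#' extractor selected by the spec, then merges duplicate documentation of
#' the same interaction (same unordered pair, type and direction) into
#' single edges carrying all supporting record ids.
#'
#' @param spec a [QuerySpec-class]
#' @param kb a [Knowledgebase-class]
#' @return an [InteractionGraph-class]
#' @examples
#' fx <- generateComplexityFixture(seed = 1)
#' spec <- parseQuery(fx$queryString, fx$kb,
#'                    resolutionOrganism = fx$resolutionTaxon,
#'                    radiusMode = "R0_INTERMEDIATES")
#' extractSubgraph(spec, fx$kb)
#' @export
extractSubgraph <- function(spec, kb) {
    qs <- effectiveQuerySet(spec, kb)
    recs <- filterRecords(kb, spec)
    fn <- switch(spec@radiusMode,
                 R0 = extractR0,
                 R0_INTERMEDIATES = extractR0Intermediates,
                 R1 = extractR1,
                 R2 = extractR2)
    g <- fn(qs, recs)
    g@groupNames <- names(spec@groups)
    g
}

#' Serialize a result graph as a JSON-lines edge list
#'
#' One JSON object per line: first a header line with the node table, then
#' one line per merged edge (gene_a, gene_b, interaction_type, directed,
#' record_ids). Intended for debugging and downstream scripting.
#'
#' @param graph an [InteractionGraph-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeEdgeList <- function(graph, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(jsonlite::toJSON(list(
        type = "nodes", nodes = graph@nodes), dataframe = "rows",
        auto_unbox = TRUE), con)
    ed <- graph@edges
    for (i in seq_len(nrow(ed)))
        writeLines(jsonlite::toJSON(list(
            type = "edge", gene_a = ed$gene_a[i], gene_b = ed$gene_b[i],
            interaction_type = ed$interaction_type[i],
            directed = ed$directed[i],
            record_ids = as.integer(ed$record_ids[[i]])),
            auto_unbox = TRUE), con)
    invisible(path)
}
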