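#' @name accessors
#' @title Accessors for netKB objects
#' @description Slot accessors for the core classes. Use these instead of
#'   `@` access; the slot layout is not part of the API.
#' @param x a netKB object
#' @return the corresponding component (a data.frame, list or character
#'   vector; see the class documentation).
NULL

#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))
#' @rdname accessors
#' @export
setGeneric("geneInfo", function(x) standardGeneric("geneInfo"))
#' @rdname accessors
#' @export
setGeneric("homologyGroups", function(x) standardGeneric("homologyGroups"))
#' @rdname accessors
#' @export
setGeneric("historyLog", function(x) standardGeneric("historyLog"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("queryMembership", function(x) standardGeneric("queryMembership"))
#' @rdname accessors
#' @export
setGeneric("queryGroups", function(x) standardGeneric("queryGroups"))
#' @rdname accessors
#' @export
setGeneric("radiusMode", function(x) standardGeneric("radiusMode"))
#' @rdname accessors
#' @export
setGeneric("organism", function(x) standardGeneric("organism"))
#' @rdname accessors
#' @export
setGeneric("stacks", function(x) standardGeneric("stacks"))
#' @rdname accessors
#' @export
setGeneric("singletons", function(x) standardGeneric("singletons"))
#' @rdname accessors
#' @export
setGeneric("dotText", function(x) standardGeneric("dotText"))
#' @rdname accessors
#' @export
setGeneric("urlMap", function(x) standardGeneric("urlMap"))
#' @rdname accessors
#' @export
setGeneric("legendItems", function(x) standardGeneric("legendItems"))

#' @rdname accessors
setMethod("interactions", "Knowledgebase", function(x) x@interactions)
#' @rdname accessors
setMethod("geneInfo", "Knowledgebase", function(x) x@genes)
#' @rdname accessors
setMethod("homologyGroups", "Knowledgebase", function(x) x@homology)
#' @rdname accessors
setMethod("historyLog", "Knowledgebase", function(x) x@history)
#' @rdname accessors
setMethod("graphNodes", "InteractionGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "InteractionGraph", function(x) x@edges)
#' @rdname accessors
setMethod("queryMembership", "InteractionGraph", function(x) x@queryMembership)
#' @rdname accessors
setMethod("queryGroups", "QuerySpec", function(x) x@groups)
#' @rdname accessors
setMethod("radiusMode", "QuerySpec", function(x) x@radiusMode)
#' @rdname accessors
setMethod("organism", "QuerySpec", function(x) x@organism)
#' @rdname accessors
setMethod("stacks", "CompoundPartition", function(x) x@stacks)
#' @rdname accessors
setMethod("singletons", "CompoundPartition", function(x) x@singletons)
#' @rdname accessors
setMethod("dotText", "DotDocument", function(x) x@dotText)
#' @rdname accessors
setMethod("urlMap", "DotDocument", function(x) x@urlMap)
#' @rdname accessors
setMethod("legendItems", "DotDocument", function(x) x@legendItems)

setMethod("show", "Knowledgebase", function(object) {
    cat(sprintf(
        "Knowledgebase: %d interactions, %d genes (%d taxa), %d ortholog groups, %d history events\n",
        nrow(object@interactions), nrow(object@genes),
        length(unique(object@genes$tax_id)),
        length(unique(object@homology$homologene_id)),
        nrow(object@history)))
})

setMethod("show", "QuerySpec", function(object) {
    org <- if (is.na(object@organism)) "all orthologs" else
        sprintf("taxon %d", object@organism)
    cat(sprintf("QuerySpec: %d group(s), radius %s, %s\n",
                length(object@groups), object@radiusMode, org))
    for (i in seq_along(object@groups))
        cat(sprintf("  %s: %s\n", names(object@groups)[i],
                    paste(object@groups[[i]], collapse = ", ")))
})

setMethod("show", "InteractionGraph", function(object) {
    cat(sprintf("InteractionGraph: %d nodes, %d merged edges\n",
                nrow(object@nodes), nrow(object@edges)))
    if (nrow(object@nodes)) {
        tab <- table(factor(object@nodes$role, levels = NODE_ROLES))
        tab <- tab[tab > 0]
        cat("  roles:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
    }
})

setMethod("show", "CompoundPartition", function(object) {
    cat(sprintf("CompoundPartition: %d stack(s), %d singleton(s)\n",
                length(object@stacks), nrow(object@singletons)))
})

setMethod("show", "DotDocument", function(object) {
    cat(sprintf("DotDocument: %d characters of DOT, %d mapped URLs, %d legend items\n",
                nchar(object@dotText), length(object@urlMap),
                nrow(object@legendItems)))
})
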