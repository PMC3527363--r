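#' Partition result-graph nodes into ortholog stacks
#'
#' Orthologous genes are drawn as one compound (stacked) node only when
#' there is a documented interaction for each of them that appears in the
#' resulting graph: two nodes share a stack iff they share an ortholog-group
#' id AND each carries at least one edge in the graph. Nodes with no
#' homology entry, whose group-mates are absent or edgeless, or which are
#' themselves edgeless (e.g. isolated query genes) are singletons. Under a
#' single-organism constraint the partition is all singletons.
#'
#' Paralogs within one taxon that share a group are stacked together: group
#' membership is the only criterion, and members are ordered by (tax_id,
#' gene_id).
#'
#' @param graph an [InteractionGraph-class]
#' @param kb a [Knowledgebase-class]
#' @param spec the [QuerySpec-class] the graph was extracted under
#' @return a [CompoundPartition-class]
#' @export
buildPartition <- function(graph, kb, spec) {
    nd <- graph@nodes
    ed <- graph@edges
    touched <- unique(c(ed$gene_a, ed$gene_b))
    singleOrg <- !is.na(spec@organism)
    hm <- kb@homology
    hid <- hm$homologene_id[match(nd$gene_id, hm$gene_id)]
    eligible <- !singleOrg & !is.na(hid) & nd$gene_id %in% touched

    stacks <- list()
    inStack <- rep(FALSE, nrow(nd))
    if (any(eligible)) {
        for (h in sort(unique(hid[eligible]))) {
            idx <- which(eligible & hid == h)
            if (length(idx) >= 2) {
                mem <- nd[idx, c("gene_id", "tax_id")]
                mem <- mem[order(mem$tax_id, mem$gene_id), , drop = FALSE]
                rownames(mem) <- NULL
                stacks[[length(stacks) + 1L]] <-
                    list(homologene_id = h, members = mem)
                inStack[idx] <- TRUE
            }
        }
    }
    sing <- nd[!inStack, c("gene_id", "tax_id"), drop = FALSE]
    sing <- sing[order(sing$tax_id, sing$gene_id), , drop = FALSE]
    rownames(sing) <- NULL
    methods::new("CompoundPartition", stacks = stacks, singletons = sing)
}
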