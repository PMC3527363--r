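## GraphViz DOT emission. One node per gene (hypernode semantics: the
## molecular role -- DNA vs protein -- is implied by each incident edge's
## type), ortholog stacks as record-shaped compound nodes (sfdp does not
## honor cluster subgraphs, so stacks are single record nodes with one port
## per member), typed edge encodings, query-group border colors, and an
## auto-generated legend in a cluster subgraph.

#' Rendering style configuration
#'
#' Colors, shapes, URL templates and layout-engine name used by [toDot()].
#' The two encodings the field expects are fixed defaults: a black line for
#' protein-protein interactions and a red arrow for protein->DNA
#' (regulator to target); genetic interactions default to a dashed blue
#' line and the catch-all type to a dotted gray line. The query-group
#' palette is a colorblind-safe three-color set.
#'
#' @param edgeColors named colors per interaction type
#' @param edgeStyles named line styles per interaction type
#' @param groupPalette three colors for query groups 1-3
#' @param geneUrlTemplate `sprintf` template for node URLs (Entrez-style
#'   gene pages)
#' @param recordUrlTemplate `sprintf` template for edge URLs; the default
#'   local anchor scheme `record://<ids>` preserves record traceability
#'   without a web service
#' @param layoutEngine layout engine name written into the document (and
#'   invoked by [renderDot()] for non-DOT formats)
#' @return a list with class `StyleConfig`
#' @export
styleConfig <- function(edgeColors = c(protein_protein = "black",
                                       protein_dna = "red",
                                       genetic = "blue",
                                       other = "gray50"),
                        edgeStyles = c(protein_protein = "solid",
                                       protein_dna = "solid",
                                       genetic = "dashed",
                                       other = "dotted"),
                        groupPalette = c("#0072B2", "#D55E00", "#009E73"),
                        geneUrlTemplate = "https://www.ncbi.nlm.nih.gov/gene/%s",
                        recordUrlTemplate = "record://%s",
                        layoutEngine = "sfdp") {
    structure(list(edgeColors = edgeColors, edgeStyles = edgeStyles,
                   groupPalette = groupPalette,
                   geneUrlTemplate = geneUrlTemplate,
                   recordUrlTemplate = recordUrlTemplate,
                   layoutEngine = layoutEngine),
              class = "StyleConfig")
}

#' Read a style configuration from a flat key=value file
#'
#' Recognized keys: `edge_color.<type>`, `edge_style.<type>`,
#' `group_color.1..3`, `gene_url_template`, `record_url_template`,
#' `layout_engine`. Unknown keys raise a configuration error. Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path config file path
#' @return a `StyleConfig`
#' @export
readStyleConfig <- function(path) {
    if (!file.exists(path))
        nkbStop("netkb_config_error", "style config not found: %s", path)
    sc <- styleConfig()
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) < 2)
            nkbStop("netkb_config_error", "malformed config line: %s", ln)
        key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
        if (grepl("^edge_color\\.", key)) {
            type <- sub("^edge_color\\.", "", key)
            if (!(type %in% INTERACTION_TYPES))
                nkbStop("netkb_config_error", "unknown interaction type: %s", type)
            sc$edgeColors[type] <- val
        } else if (grepl("^edge_style\\.", key)) {
            type <- sub("^edge_style\\.", "", key)
            if (!(type %in% INTERACTION_TYPES))
                nkbStop("netkb_config_error", "unknown interaction type: %s", type)
            sc$edgeStyles[type] <- val
        } else if (grepl("^group_color\\.[123]$", key)) {
            sc$groupPalette[as.integer(sub("^group_color\\.", "", key))] <- val
        } else if (key == "gene_url_template") {
            sc$geneUrlTemplate <- val
        } else if (key == "record_url_template") {
            sc$recordUrlTemplate <- val
        } else if (key == "layout_engine") {
            sc$layoutEngine <- val
        } else {
            nkbStop("netkb_config_error", "unknown config key: %s", key)
        }
    }
    sc
}

escapeDot <- function(x) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    gsub("\"", "\\\"", x, fixed = TRUE)
}

## record-label fields additionally reserve | { } < >
escapeRecordField <- function(x) {
    x <- escapeDot(x)
    gsub("([|{}<>])", "\\\\\\1", x)
}

attrList <- function(...) {
    kv <- c(...)
    paste0("[", paste(sprintf("%s=\"%s\"", names(kv), escapeDot(unname(kv))),
                      collapse = ", "), "]")
}

EDGE_TYPE_LABELS <- c(protein_protein = "protein-protein interaction",
                      protein_dna = "protein->DNA interaction",
                      genetic = "genetic interaction",
                      other = "other interaction")

#' Build the legend entries for a result graph
#'
#' One entry per edge encoding actually present in the graph (in the fixed
#' enumeration order protein-protein, protein->DNA, genetic, other), plus
#' one entry per query group when there are two or more groups or any group
#' was renamed from its default.
#'
#' @param graph an [InteractionGraph-class]
#' @param spec the [QuerySpec-class] it was extracted under
#' @param style a `StyleConfig`
#' @return data.frame with columns glyph and label
#' @export
buildLegend <- function(graph, spec, style = styleConfig()) {
    items <- data.frame(glyph = character(0), label = character(0))
    present <- INTERACTION_TYPES[INTERACTION_TYPES %in%
                                 graph@edges$interaction_type]
    for (tp in present) {
        arrow <- if (tp == "protein_dna") "arrow" else "line"
        items <- rbind(items, data.frame(
            glyph = sprintf("%s %s %s", style$edgeStyles[[tp]],
                            style$edgeColors[[tp]], arrow),
            label = EDGE_TYPE_LABELS[[tp]]))
    }
    nm <- names(spec@groups)
    showGroups <- length(nm) >= 2 ||
        any(nm != sprintf("Query Group %d", seq_along(nm)))
    if (showGroups) {
        for (i in seq_along(nm))
            items <- rbind(items, data.frame(
                glyph = sprintf("box colored %s", style$groupPalette[i]),
                label = nm[i]))
    }
    rownames(items) <- NULL
    items
}

#' Render a result graph and its ortholog partition to DOT
#'
#' Emits a `digraph` whose body contains exactly one node statement per
#' partition element (singleton genes as ellipses, ortholog stacks as
#' record-shaped nodes with one port per member) and one edge statement per
#' merged edge. Protein-protein interactions are undirected black lines,
#' protein->DNA interactions red arrows pointing at the target, genetic and
#' other types use the configured encodings. Query-group membership is
#' drawn as a colored node border (lowest group index's color, with a
#' double-periphery marker for multi-group nodes). The layout-engine hint
#' and an auto-generated legend cluster are written into the document.
#' Every node, stack member and edge carries a URL attribute, repeated in
#' the document's URL map for clickable output.
#'
#' Output is deterministic: identical inputs yield byte-identical DOT text.
#'
#' @param graph an [InteractionGraph-class]
#' @param partition a [CompoundPartition-class] for the same graph
#' @param spec the [QuerySpec-class] the graph was extracted under
#' @param kb the [Knowledgebase-class] (for symbols and submitter names)
#' @param style a `StyleConfig`
#' @return a [DotDocument-class]
#' @export
toDot <- function(graph, partition, spec, kb, style = styleConfig()) {
    nd <- graph@nodes
    part_ids <- c(unlist(lapply(partition@stacks,
                                function(s) s$members$gene_id)),
                  partition@singletons$gene_id)
    if (!setequal(part_ids, nd$gene_id) ||
        length(part_ids) != nrow(nd))
        nkbStop("netkb_integrity_error",
                "partition is not a partition of the graph's nodes")

    ## gene -> DOT element reference (node id, or stack port for members)
    nodeRef <- character(0)
    urlMap <- character(0)
    lines <- c("digraph interactome {",
               sprintf("  graph [layout=\"%s\", overlap=\"prism\"];",
                       style$layoutEngine),
               "  node [shape=\"ellipse\", fontsize=\"10\"];")

    memb <- graph@queryMembership
    groupAttrs <- function(geneIds) {
        gs <- sort(unique(unlist(memb[as.character(geneIds)])))
        if (length(gs) == 0) return(character(0))
        att <- c(color = style$groupPalette[gs[1]], penwidth = "2")
        if (length(gs) > 1) att <- c(att, peripheries = "2")
        att
    }

    ## stacks first (ordered by group id), then singleton nodes
    for (s in partition@stacks) {
        sid <- sprintf("hg%d", s$homologene_id)
        mem <- s$members
        fields <- sprintf("<p%d> %s [%d]", mem$gene_id,
                          escapeRecordField(symbolOf(mem$gene_id, kb)),
                          mem$tax_id)
        att <- c(shape = "record",
                 URL = sprintf(style$geneUrlTemplate, mem$gene_id[1]),
                 groupAttrs(mem$gene_id))
        ## label fields are pre-escaped for the record grammar, so the
        ## label attribute is written outside attrList (which re-escapes)
        attStr <- attrList(att)
        attStr <- sub("\\]$", sprintf(", label=\"%s\"]",
                                      paste(fields, collapse = "|")), attStr)
        lines <- c(lines, sprintf("  %s %s;", sid, attStr))
        urlMap[sid] <- sprintf(style$geneUrlTemplate, mem$gene_id[1])
        for (i in seq_len(nrow(mem))) {
            ref <- sprintf("%s:p%d", sid, mem$gene_id[i])
            nodeRef[as.character(mem$gene_id[i])] <- ref
            urlMap[ref] <- sprintf(style$geneUrlTemplate, mem$gene_id[i])
        }
    }
    sing <- partition@singletons
    for (i in seq_len(nrow(sing))) {
        g <- sing$gene_id[i]
        nid <- sprintf("g%d", g)
        url <- sprintf(style$geneUrlTemplate, g)
        att <- c(label = symbolOf(g, kb), URL = url, groupAttrs(g))
        lines <- c(lines, sprintf("  %s %s;", nid, attrList(att)))
        nodeRef[as.character(g)] <- nid
        urlMap[nid] <- url
    }

    ## merged edges; submitter attribution from the underlying records
    ix <- kb@interactions
    ed <- graph@edges
    for (i in seq_len(nrow(ed))) {
        rids <- ed$record_ids[[i]]
        eid <- sprintf("e%s", paste(rids, collapse = "_"))
        url <- sprintf(style$recordUrlTemplate,
                       paste(rids, collapse = "+"))
        subs <- unique(ix$submitter[match(rids, ix$record_id)])
        subs <- subs[!is.na(subs) & nzchar(subs)]
        tp <- ed$interaction_type[i]
        att <- c(id = eid,
                 color = style$edgeColors[[tp]],
                 style = style$edgeStyles[[tp]],
                 URL = url)
        if (!ed$directed[i]) att <- c(att, dir = "none")
        if (length(subs)) {
            att <- c(att, tooltip = sprintf("submitted by %s",
                                            paste(subs, collapse = ", ")))
            url <- paste0(url, "?submitter=",
                          paste(subs, collapse = ","))
        }
        att["URL"] <- url
        lines <- c(lines, sprintf("  %s -> %s %s;",
                                  nodeRef[as.character(ed$gene_a[i])],
                                  nodeRef[as.character(ed$gene_b[i])],
                                  attrList(att)))
        urlMap[eid] <- url
    }

    ## legend cluster: a styled sample edge per encoding, a colored box per
    ## named query group
    legend <- buildLegend(graph, spec, style)
    lines <- c(lines, "  subgraph cluster_legend {",
               "    label=\"Legend\";", "    fontsize=\"10\";")
    li <- 0L
    for (j in seq_len(nrow(legend))) {
        li <- li + 1L
        if (grepl("line$|arrow$", legend$glyph[j])) {
            tp <- names(EDGE_TYPE_LABELS)[match(legend$label[j],
                                                EDGE_TYPE_LABELS)]
            att <- c(color = style$edgeColors[[tp]],
                     style = style$edgeStyles[[tp]],
                     label = legend$label[j], fontsize = "9")
            if (tp != "protein_dna") att <- c(att, dir = "none")
            lines <- c(lines,
                sprintf("    lg%da [shape=\"point\", width=\"0.05\"];", li),
                sprintf("    lg%db [shape=\"point\", width=\"0.05\"];", li),
                sprintf("    lg%da -> lg%db %s;", li, li, attrList(att)))
        } else {
            lines <- c(lines, sprintf("    lg%d %s;", li,
                attrList(c(shape = "box", label = legend$label[j],
                           color = sub("^box colored ", "", legend$glyph[j]),
                           penwidth = "2", fontsize = "9"))))
        }
    }
    lines <- c(lines, "  }", "}")
    methods::new("DotDocument", dotText = paste(lines, collapse = "\n"),
                 urlMap = urlMap, legendItems = legend)
}

#' Write a DOT document, optionally rendering through GraphViz
#'
#' `format = "dot"` writes the DOT text verbatim and is always available.
#' The raster/vector formats shell out to the configured layout engine
#' (default sfdp) and raise a named environment error when no GraphViz
#' executable is discoverable; `gif_with_cmap` additionally writes the
#' clickable CMAP image-map sidecar next to the image.
#'
#' @param doc a [DotDocument-class]
#' @param format one of dot, gif_with_cmap, pdf, svg
#' @param out output file path
#' @param style a `StyleConfig` (names the layout engine)
#' @return `out`, invisibly
#' @export
renderDot <- function(doc, format = c("dot", "gif_with_cmap", "pdf", "svg"),
                      out, style = styleConfig()) {
    format <- match.arg(format)
    if (format == "dot") {
        writeLines(doc@dotText, out, sep = "")
        cat("\n", file = out, append = TRUE)
        return(invisible(out))
    }
    engine <- Sys.which(style$layoutEngine)
    if (!nzchar(engine))
        nkbStop("netkb_environment_error",
                "GraphViz layout engine '%s' not found on PATH; install GraphViz to render %s output",
                style$layoutEngine, format)
    src <- tempfile(fileext = ".dot")
    on.exit(unlink(src))
    writeLines(doc@dotText, src)
    gvFormat <- c(gif_with_cmap = "gif", pdf = "pdf", svg = "svg")[[format]]
    status <- system2(engine, c(paste0("-T", gvFormat), "-o", shQuote(out),
                                shQuote(src)))
    if (status != 0)
        nkbStop("netkb_environment_error", "%s exited with status %d",
                style$layoutEngine, status)
    if (format == "gif_with_cmap") {
        mapOut <- paste0(out, ".map")
        status <- system2(engine, c("-Tcmapx", "-o", shQuote(mapOut),
                                    shQuote(src)))
        if (status != 0)
            nkbStop("netkb_environment_error",
                    "%s exited with status %d while writing CMAP",
                    style$layoutEngine, status)
    }
    invisible(out)
}
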