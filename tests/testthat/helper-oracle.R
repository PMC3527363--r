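# Independent brute-force oracles. Deliberately written as naive per-record
# loops and adjacency scans (no shared code with the package's vectorized
# extractors) so the two routes can disagree.

# returns list(records = sorted record ids, nodes = sorted gene ids)
oracleExtract <- function(mode, qs, records) {
    qs <- as.integer(qs)
    keep <- logical(nrow(records))
    extraNodes <- integer(0)
    inQ <- function(g) g %in% qs
    if (mode == "R0") {
        for (i in seq_len(nrow(records)))
            keep[i] <- inQ(records$gene_a[i]) && inQ(records$gene_b[i])
    } else if (mode == "R1") {
        for (i in seq_len(nrow(records)))
            keep[i] <- inQ(records$gene_a[i]) || inQ(records$gene_b[i])
    } else if (mode == "R0_INTERMEDIATES") {
        # query neighbors of every outside gene, by plain scan
        nbrs <- new.env()
        for (i in seq_len(nrow(records))) {
            a <- records$gene_a[i]; b <- records$gene_b[i]
            if (inQ(a) && !inQ(b)) {
                k <- as.character(b)
                assign(k, union(mget(k, nbrs, ifnotfound = list(integer(0)))[[1]], a), nbrs)
            }
            if (inQ(b) && !inQ(a)) {
                k <- as.character(a)
                assign(k, union(mget(k, nbrs, ifnotfound = list(integer(0)))[[1]], b), nbrs)
            }
        }
        inter <- as.integer(Filter(
            function(k) length(get(k, nbrs)) >= 2, ls(nbrs)))
        for (i in seq_len(nrow(records))) {
            a <- records$gene_a[i]; b <- records$gene_b[i]
            keep[i] <- (inQ(a) && inQ(b)) ||
                (inQ(a) && b %in% inter) || (inQ(b) && a %in% inter)
        }
    } else if (mode == "R2") {
        # distance-limited membership via igraph as an independent route
        if (nrow(records)) {
            verts <- as.character(sort(unique(c(records$gene_a,
                                                records$gene_b, qs))))
            g <- igraph::graph_from_data_frame(
                data.frame(from = as.character(records$gene_a),
                           to = as.character(records$gene_b)),
                directed = FALSE, vertices = verts)
            qv <- as.character(qs[as.character(qs) %in% verts])
            d <- igraph::distances(g, v = qv, mode = "all")
            mind <- apply(d, 2, min)
            near <- names(mind)[mind <= 1]
            for (i in seq_len(nrow(records)))
                keep[i] <- as.character(records$gene_a[i]) %in% near ||
                    as.character(records$gene_b[i]) %in% near
        }
    } else stop("unknown mode")
    sel <- records[keep, , drop = FALSE]
    list(records = sort(sel$record_id),
         nodes = sort(unique(c(qs, sel$gene_a, sel$gene_b))))
}

# brute-force ortholog expansion: scan the homology table per query gene
oracleExpand <- function(geneIds, kb) {
    hm <- homologyGroups(kb)
    out <- integer(0)
    for (g in geneIds) {
        hit <- g
        for (i in seq_len(nrow(hm)))
            if (hm$gene_id[i] == g) {
                hid <- hm$homologene_id[i]
                hit <- hm$gene_id[hm$homologene_id == hid]
            }
        out <- union(out, hit)
    }
    sort(out)
}

# brute-force stacking: group nodes by (homologene id, has an edge)
oraclePartition <- function(graph, kb) {
    nd <- graphNodes(graph)
    ed <- graphEdges(graph)
    hm <- homologyGroups(kb)
    touched <- unique(c(ed$gene_a, ed$gene_b))
    byGroup <- split(nd$gene_id,
                     hm$homologene_id[match(nd$gene_id, hm$gene_id)])
    stacksOf <- lapply(byGroup, function(g) sort(g[g %in% touched]))
    stacksOf <- Filter(function(g) length(g) >= 2, stacksOf)
    stacked <- unlist(stacksOf, use.names = FALSE)
    list(stacks = unname(stacksOf[order(as.integer(names(stacksOf)))]),
         singletons = sort(setdiff(nd$gene_id, stacked)))
}

# brute-force keyword hits: scan every gene's four fields
oracleLookup <- function(keyword, kb, organism = NULL) {
    gn <- geneInfo(kb)
    kw <- tolower(keyword)
    hits <- integer(0)
    for (i in seq_len(nrow(gn))) {
        if (!is.null(organism) && gn$tax_id[i] != organism) next
        fields <- c(gn$description[i], gn$symbol[i],
                    strsplit(gn$go_terms[i], "|", fixed = TRUE)[[1]],
                    strsplit(gn$synonyms[i], "|", fixed = TRUE)[[1]])
        if (any(grepl(kw, tolower(fields), fixed = TRUE)))
            hits <- c(hits, gn$gene_id[i])
    }
    sort(hits)
}

# --- minimal DOT grammar checker -------------------------------------------
# Recursive-descent parser over a tokenized DOT document. Validates the
# grammar subset the renderer may emit and counts top-level node and edge
# statements (legend statements live inside a subgraph and are counted
# separately).

dotTokenize <- function(text) {
    tokens <- character(0)
    i <- 1L; n <- nchar(text)
    while (i <= n) {
        ch <- substr(text, i, i)
        if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
        if (ch == "\"") {
            j <- i + 1L
            while (j <= n) {
                cj <- substr(text, j, j)
                if (cj == "\\") { j <- j + 2L; next }
                if (cj == "\"") break
                j <- j + 1L
            }
            if (j > n) stop("unterminated quoted string")
            tokens <- c(tokens, substr(text, i, j))
            i <- j + 1L
        } else if (substr(text, i, i + 1L) == "->") {
            tokens <- c(tokens, "->"); i <- i + 2L
        } else if (ch %in% c("{", "}", "[", "]", ";", "=", ",", ":")) {
            tokens <- c(tokens, ch); i <- i + 1L
        } else if (grepl("[A-Za-z0-9_<>.#$]", ch)) {
            j <- i
            while (j <= n && grepl("[A-Za-z0-9_<>.#$]", substr(text, j, j)))
                j <- j + 1L
            tokens <- c(tokens, substr(text, i, j - 1L))
            i <- j
        } else stop(sprintf("unexpected character '%s' at %d", ch, i))
    }
    tokens
}

# parses and returns list(nodes = top-level node statement count,
#                         edges = top-level edge statement count,
#                         subgraphs = number of subgraphs)
checkDot <- function(text) {
    toks <- dotTokenize(text)
    pos <- 1L
    peek <- function() if (pos <= length(toks)) toks[pos] else ""
    take <- function(expected = NULL) {
        if (pos > length(toks)) stop("unexpected end of input")
        t <- toks[pos]; pos <<- pos + 1L
        if (!is.null(expected) && !(t %in% expected))
            stop(sprintf("expected %s, got '%s'",
                         paste(expected, collapse = "|"), t))
        t
    }
    isId <- function(t) nzchar(t) &&
        !(t %in% c("{", "}", "[", "]", ";", "=", ",", ":", "->"))
    parseAttrs <- function() {
        take("[")
        while (peek() != "]") {
            stopifnot(isId(take()))  # key
            take("=")
            stopifnot(isId(take()))  # value
            if (peek() == ",") take()
        }
        take("]")
    }
    parseBody <- function() {
        counts <- c(nodes = 0L, edges = 0L, subgraphs = 0L)
        take("{")
        while (peek() != "}") {
            t <- take()
            if (t == "subgraph") {
                stopifnot(isId(take()))  # subgraph name
                sub <- parseBody()
                counts["subgraphs"] <- counts["subgraphs"] + 1L + sub[["subgraphs"]]
                next
            }
            stopifnot(isId(t))
            if (peek() == "=") {        # graph-level attribute
                take("="); stopifnot(isId(take()))
                if (peek() == ";") take()
                next
            }
            if (t %in% c("graph", "node", "edge") && peek() == "[") {
                parseAttrs()            # default attribute statement
                if (peek() == ";") take()
                next
            }
            if (peek() == ":") { take(); stopifnot(isId(take())) }  # port
            if (peek() == "->") {
                while (peek() == "->") {
                    take("->")
                    stopifnot(isId(take()))
                    if (peek() == ":") { take(); stopifnot(isId(take())) }
                }
                if (peek() == "[") parseAttrs()
                counts["edges"] <- counts["edges"] + 1L
            } else {
                if (peek() == "[") parseAttrs()
                counts["nodes"] <- counts["nodes"] + 1L
            }
            if (peek() == ";") take()
        }
        take("}")
        counts
    }
    take(c("digraph", "graph"))
    if (peek() != "{") stopifnot(nzchar(take()))  # optional graph name
    counts <- parseBody()
    if (pos <= length(toks)) stop("trailing tokens after closing brace")
    as.list(counts)
}
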