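## Identifier resolution. Queries are conducted with Entrez-style gene ids,
## official symbols, or unofficial synonyms; synonyms are accepted only when
## they match unambiguously. Precedence: numeric id > official symbol >
## synonym. Symbol/synonym matching is case-insensitive and, when an
## organism is given, restricted to that taxon.

resolutionReport <- function(token, outcome, candidates = NULL) {
    if (is.null(candidates))
        candidates <- data.frame(gene_id = integer(0), tax_id = integer(0))
    structure(list(token = token, outcome = outcome,
                   candidates = candidates),
              class = "ResolutionReport")
}

#' @export
print.ResolutionReport <- function(x, ...) {
    cat(sprintf("token '%s': %s", x$token, x$outcome))
    if (nrow(x$candidates))
        cat(" [", paste(x$candidates$gene_id, collapse = ", "), "]", sep = "")
    cat("\n")
    invisible(x)
}

#' Resolve one query token to a gene
#'
#' Resolution precedence is numeric id, then official symbol, then synonym:
#' a token of digits is looked up as a gene id (a gene whose official symbol
#' happens to be purely numeric is reachable only by id); otherwise official
#' symbols are tried, then synonyms, both case-insensitively and restricted
#' to `organism` when one is given. A token matching two or more genes in
#' scope is reported `ambiguous` with all candidates, never silently picked;
#' a synonym that is also some gene's official symbol resolves to the
#' official symbol. Without an organism, a symbol matching exactly one gene
#' across all taxa still resolves; an organism is only required when the
#' match is genuinely ambiguous.
#'
#' @param token query token (trimmed of surrounding whitespace)
#' @param kb a [Knowledgebase-class]
#' @param organism optional taxon id restricting symbol/synonym scope
#' @return a `ResolutionReport`: list with `token`, `outcome` (one of
#'   resolved_id, resolved_symbol, resolved_synonym, ambiguous, unknown) and
#'   a `candidates` data.frame (gene_id, tax_id); resolved outcomes have
#'   exactly one candidate, ambiguous at least two
#' @export
resolveToken <- function(token, kb, organism = NULL) {
    token <- trimws(token)
    if (!nzchar(token))
        nkbStop("netkb_query_format_error", "empty query token")
    gn <- kb@genes
    if (!is.null(organism) && !is.na(organism))
        gn <- gn[gn$tax_id == organism, , drop = FALSE]
    cand <- function(rows)
        data.frame(gene_id = rows$gene_id, tax_id = rows$tax_id)

    if (grepl("^[0-9]+$", token)) {
        hit <- kb@genes[kb@genes$gene_id == as.integer(token), , drop = FALSE]
        if (nrow(hit) == 1)
            return(resolutionReport(token, "resolved_id", cand(hit)))
        ## ids also resolve when the gene appears only in the interaction
        ## table (tolerated orphans)
        ix <- kb@interactions
        asA <- ix$gene_a == as.integer(token)
        asB <- ix$gene_b == as.integer(token)
        if (any(asA) || any(asB)) {
            tax <- c(ix$tax_a[asA], ix$tax_b[asB])[1]
            return(resolutionReport(token, "resolved_id",
                data.frame(gene_id = as.integer(token), tax_id = tax)))
        }
        return(resolutionReport(token, "unknown"))
    }

    sym <- gn[tolower(gn$symbol) == tolower(token), , drop = FALSE]
    if (nrow(sym) == 1)
        return(resolutionReport(token, "resolved_symbol", cand(sym)))
    if (nrow(sym) >= 2)
        return(resolutionReport(token, "ambiguous", cand(sym)))

    hasSyn <- vapply(splitPipe(gn$synonyms), function(s)
        any(tolower(s) == tolower(token)), logical(1))
    syn <- gn[hasSyn, , drop = FALSE]
    if (nrow(syn) == 1)
        return(resolutionReport(token, "resolved_synonym", cand(syn)))
    if (nrow(syn) >= 2)
        return(resolutionReport(token, "ambiguous", cand(syn)))
    resolutionReport(token, "unknown")
}

#' Parse a multi-group query string into a QuerySpec
#'
#' The query grammar is `group ("/" group){0,2}` with `group := token (","
#' token)*`: a comma-separated list is one query group, and up to three
#' groups may be separated by forward slashes. Whitespace around tokens is
#' ignored; a trailing comma is forgiven; an empty group between slashes or
#' more than three groups is a format error. Every token must resolve (see
#' [resolveToken()]); otherwise a resolution error carrying all reports is
#' raised — tokens are never silently dropped. Default group names are
#' "Query Group 1" through "Query Group 3".
#'
#' @param queryString the query text, e.g. `"Oct4, Sox2/Nanog, Lin28A"`
#' @param kb a [Knowledgebase-class]
#' @param organism optional taxon id: confines the query to a single
#'   organism (disabling ortholog expansion) and scopes symbol resolution
#' @param resolutionOrganism optional taxon id scoping symbol/synonym
#'   resolution only, for all-ortholog queries entered with one organism's
#'   symbols; defaults to `organism`
#' @param radiusMode one of `"R0"`, `"R0_INTERMEDIATES"`, `"R1"`, `"R2"`
#' @param groupNames optional character vector overriding default group names
#' @param includeTypes interaction types to keep (default all)
#' @param includeStatus annotation statuses to keep (default all)
#' @return a [QuerySpec-class]; the per-token `ResolutionReport`s are
#'   available via `resolutionReports()`
#' @examples
#' fx <- generateComplexityFixture(seed = 1)
#' spec <- parseQuery("HUB1, HUB2", fx$kb, organism = fx$singleTaxon)
#' spec
#' @export
parseQuery <- function(queryString, kb, organism = NULL,
                       resolutionOrganism = organism,
                       radiusMode = c("R1", "R0", "R0_INTERMEDIATES", "R2"),
                       groupNames = NULL,
                       includeTypes = INTERACTION_TYPES,
                       includeStatus = ANNOTATION_STATUSES) {
    radiusMode <- match.arg(radiusMode)
    if (!nzchar(trimws(queryString)))
        nkbStop("netkb_query_format_error", "empty query string")
    segs <- strsplit(queryString, "/", fixed = TRUE)[[1]]
    if (length(segs) > 3)
        nkbStop("netkb_query_format_error",
                "at most 3 query groups allowed, got %d", length(segs))
    groups <- vector("list", length(segs))
    reports <- list()
    for (i in seq_along(segs)) {
        toks <- trimws(strsplit(segs[i], ",", fixed = TRUE)[[1]])
        toks <- toks[nzchar(toks)]  # forgive trailing/duplicated commas
        if (length(toks) == 0)
            nkbStop("netkb_query_format_error",
                    "query group %d is empty", i)
        rep_i <- lapply(toks, resolveToken, kb = kb,
                        organism = resolutionOrganism)
        reports <- c(reports, rep_i)
        groups[[i]] <- vapply(rep_i, function(r)
            if (startsWith(r$outcome, "resolved")) r$candidates$gene_id[1]
            else NA_integer_, integer(1))
    }
    failed <- vapply(reports, function(r)
        !startsWith(r$outcome, "resolved"), logical(1))
    if (any(failed)) {
        msgs <- vapply(reports[failed], function(r)
            sprintf("'%s': %s", r$token, r$outcome), "")
        nkbStop("netkb_resolution_error",
                "unresolved query token(s): %s", paste(msgs, collapse = "; "),
                data = reports)
    }
    nm <- sprintf("Query Group %d", seq_along(groups))
    if (!is.null(groupNames)) {
        if (length(groupNames) < length(groups))
            nkbStop("netkb_usage_error",
                    "%d group names given for %d groups",
                    length(groupNames), length(groups))
        nm <- groupNames[seq_along(groups)]
    }
    names(groups) <- nm
    spec <- methods::new("QuerySpec", groups = groups,
                         radiusMode = radiusMode,
                         organism = if (is.null(organism)) NA_integer_
                                    else as.integer(organism),
                         includeTypes = includeTypes,
                         includeStatus = includeStatus)
    attr(spec, "reports") <- reports
    spec
}

#' Resolution reports attached to a parsed QuerySpec
#' @param spec a [QuerySpec-class] returned by [parseQuery()]
#' @return list of `ResolutionReport`s, one per query token
#' @export
resolutionReports <- function(spec) attr(spec, "reports")

#' Format a QuerySpec back to its canonical query string
#'
#' Members are written as official symbols (raw ids for unannotated genes),
#' groups joined with "/". `parseQuery(formatQuery(spec))` reproduces the
#' groups whenever the symbols are unambiguous in the resolution scope.
#'
#' @param spec a [QuerySpec-class]
#' @param kb a [Knowledgebase-class]
#' @return single character string
#' @export
formatQuery <- function(spec, kb) {
    paste(vapply(spec@groups, function(g)
        paste(symbolOf(g, kb), collapse = ", "), ""), collapse = "/")
}

#' Expand gene ids across their ortholog groups
#'
#' Each queried gene maps to itself plus every gene sharing its
#' HomoloGene-style group id; genes with no homology entry map to the
#' singleton set containing themselves. The expansion is idempotent.
#'
#' @param geneIds integer vector of resolved gene ids
#' @param kb a [Knowledgebase-class]
#' @return named list: gene id -> data.frame (gene_id, tax_id) of the
#'   expansion, ordered by (tax_id, gene_id)
#' @export
expandOrthologs <- function(geneIds, kb) {
    hm <- kb@homology
    out <- lapply(geneIds, function(g) {
        hid <- hm$homologene_id[match(g, hm$gene_id)]
        if (is.na(hid)) {
            tax <- taxOf(g, kb)
            df <- data.frame(gene_id = as.integer(g), tax_id = tax)
        } else {
            mem <- hm[hm$homologene_id == hid, , drop = FALSE]
            df <- data.frame(gene_id = mem$gene_id, tax_id = mem$tax_id)
        }
        df <- df[order(df$tax_id, df$gene_id), , drop = FALSE]
        rownames(df) <- NULL
        df
    })
    names(out) <- as.character(geneIds)
    out
}
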