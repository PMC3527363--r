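#' Keyword search over gene annotation (the gene lookup tool)
#'
#' Searches one keyword simultaneously against gene descriptions, GO terms,
#' official symbols and unofficial synonyms, case-insensitively and as a
#' contiguous substring (so a multi-word keyword matches as a phrase).
#' Intended for finding query candidates for unfamiliar symbols, and for
#' spotting genes with no documented interactions before querying them.
#'
#' @param keyword non-empty search phrase
#' @param kb a [Knowledgebase-class]
#' @param organism optional taxon id restricting the search scope
#' @return data.frame with one row per matched gene: gene_id, tax_id,
#'   symbol, matched_fields (comma-joined subset of
#'   description/go_term/symbol/synonym), n_fields, and supported_by_kb
#'   (TRUE iff the gene participates in at least one interaction record).
#'   Sorted by number of matched fields (descending), then gene_id.
#' @examples
#' kb <- generateFixture(40, 2, 60, seed = 3)
#' head(keywordSearch("cardiac muscle", kb))
#' @export
keywordSearch <- function(keyword, kb, organism = NULL) {
    if (!nzchar(trimws(keyword)))
        nkbStop("netkb_usage_error", "empty keyword")
    kw <- tolower(trimws(keyword))
    gn <- kb@genes
    if (!is.null(organism) && !is.na(organism))
        gn <- gn[gn$tax_id == organism, , drop = FALSE]

    hasKw <- function(x) grepl(kw, tolower(x), fixed = TRUE)
    inList <- function(parts) vapply(parts, function(v)
        any(hasKw(v)), logical(1))

    mDesc <- hasKw(gn$description)
    mGo <- if (nrow(gn)) inList(splitPipe(gn$go_terms)) else logical(0)
    mSym <- hasKw(gn$symbol)
    mSyn <- if (nrow(gn)) inList(splitPipe(gn$synonyms)) else logical(0)
    m <- mDesc | mGo | mSym | mSyn
    hit <- gn[m, , drop = FALSE]
    fields <- mapply(function(d, g, s, y)
        paste(c("description", "go_term", "symbol", "synonym")[c(d, g, s, y)],
              collapse = ","),
        mDesc[m], mGo[m], mSym[m], mSyn[m])
    nf <- mDesc[m] + mGo[m] + mSym[m] + mSyn[m]
    ix <- kb@interactions
    supported <- hit$gene_id %in% c(ix$gene_a, ix$gene_b)
    out <- data.frame(gene_id = hit$gene_id, tax_id = hit$tax_id,
                      symbol = hit$symbol,
                      matched_fields = as.character(fields),
                      n_fields = as.integer(nf),
                      supported_by_kb = supported,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$n_fields, out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Genes annotated with a GO term containing a substring
#'
#' Returns the ids of genes carrying at least one GO term that contains the
#' given substring (case-insensitive), optionally restricted to one taxon.
#' The result is suitable as a query-group member list, e.g. to build an
#' interactome for every gene annotated with "alcohol" or "bone".
#'
#' @param termSubstring non-empty substring to match against GO terms
#' @param kb a [Knowledgebase-class]
#' @param organism optional taxon id
#' @return sorted integer vector of gene ids
#' @export
goTermGeneList <- function(termSubstring, kb, organism = NULL) {
    hits <- keywordSearch(termSubstring, kb, organism)
    sort(hits$gene_id[grepl("go_term", hits$matched_fields)])
}
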