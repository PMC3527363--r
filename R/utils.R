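## Structured conditions: user-facing failures carry a class so the CLI can
## map them to exit codes without matching message text.
nkbStop <- function(class, fmt, ..., data = NULL) {
    cond <- structure(
        class = c(class, "netkb_error", "error", "condition"),
        list(message = sprintf(fmt, ...), call = sys.call(-1), data = data))
    stop(cond)
}

isUserError <- function(cond) {
    inherits(cond, c("netkb_parse_error", "netkb_integrity_error",
                     "netkb_query_format_error", "netkb_resolution_error",
                     "netkb_config_error", "netkb_usage_error"))
}

parsePubmed <- function(x) lapply(strsplit(x, ","), function(p) as.integer(p))

## split a pipe-joined annotation field; "" -> character(0)
splitPipe <- function(x) {
    out <- strsplit(x, "|", fixed = TRUE)
    lapply(out, function(v) v[nzchar(v)])
}

joinPipe <- function(x) vapply(x, paste, "", collapse = "|")

## deterministic local RNG: run f under a seed, restore global state
withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## official symbol, falling back to the raw id for unannotated genes
symbolOf <- function(geneIds, kb) {
    gn <- kb@genes
    idx <- match(geneIds, gn$gene_id)
    out <- gn$symbol[idx]
    out[is.na(idx)] <- as.character(geneIds[is.na(idx)])
    out
}

taxOf <- function(geneIds, kb) {
    gn <- kb@genes
    gn$tax_id[match(geneIds, gn$gene_id)]
}
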