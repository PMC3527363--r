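## Crowdsourced curation: users pre-submit a proposed interaction, the
## engine checks it for redundancy against the knowledgebase and reports
## back (green light / redundancy warning / invalid), and committed
## submissions are tagged with the submitter's name and logged in an
## append-only history that supports reverting to an earlier state.

#' Construct an interaction proposal
#'
#' @param geneA,taxA,geneB,taxB subject and object gene/taxon ids
#' @param interactionType one of protein_protein, protein_dna, genetic,
#'   other; protein_dna is directed subject -> object (regulator to target)
#' @param pubmedIds integer vector of supporting PubMed ids (non-empty)
#' @param submitter registered submitter name
#' @return a list with class `SubmissionProposal`
#' @export
interactionProposal <- function(geneA, taxA, geneB, taxB,
                                interactionType, pubmedIds, submitter) {
    structure(list(gene_a = as.integer(geneA), tax_a = as.integer(taxA),
                   gene_b = as.integer(geneB), tax_b = as.integer(taxB),
                   interaction_type = as.character(interactionType),
                   pubmed_ids = as.integer(pubmedIds),
                   submitter = as.character(submitter)),
              class = "SubmissionProposal")
}

## rows of the interaction table redundant with a proposal: same unordered
## gene pair and same type; for the directed type the direction (ordered
## pair) must also match
redundantRecords <- function(proposal, ix) {
    sameType <- ix$interaction_type == proposal$interaction_type
    if (proposal$interaction_type == "protein_dna") {
        hit <- sameType & ix$gene_a == proposal$gene_a &
            ix$gene_b == proposal$gene_b
    } else {
        hit <- sameType &
            ((ix$gene_a == proposal$gene_a & ix$gene_b == proposal$gene_b) |
             (ix$gene_a == proposal$gene_b & ix$gene_b == proposal$gene_a))
    }
    ix$record_id[hit]
}

#' Pre-submission check of a proposed interaction
#'
#' Validates the proposal's fields and searches the knowledgebase for
#' redundant documentation (same unordered gene pair and interaction type;
#' same direction for protein->DNA). Never throws for a bad proposal: field
#' failures yield status `invalid`, an existing match yields
#' `redundant_warning` with the matching record ids, and a novel valid
#' proposal gets the `green_light`. The messages echo the resolved official
#' gene symbols and the proposal's PubMed ids, so the submitter can confirm
#' the ids they supplied name the genes they meant. The knowledgebase is
#' never modified.
#'
#' @param proposal a `SubmissionProposal`
#' @param kb a [Knowledgebase-class]
#' @param registry optional character vector of registered submitter names;
#'   when given, an unregistered submitter makes the proposal invalid
#' @return a list with class `SubmissionVerdict`: status (green_light /
#'   redundant_warning / invalid), matches (record ids), messages
#' @export
precheckSubmission <- function(proposal, kb, registry = NULL) {
    msgs <- character(0)
    bad <- character(0)
    if (!length(proposal$pubmed_ids) || anyNA(proposal$pubmed_ids) ||
        any(proposal$pubmed_ids <= 0))
        bad <- c(bad, "one or more positive PubMed ids required")
    if (!(proposal$interaction_type %in% INTERACTION_TYPES))
        bad <- c(bad, sprintf("unknown interaction type '%s'",
                              proposal$interaction_type))
    if (anyNA(c(proposal$gene_a, proposal$gene_b, proposal$tax_a,
                proposal$tax_b)) ||
        any(c(proposal$gene_a, proposal$gene_b, proposal$tax_a,
              proposal$tax_b) <= 0, na.rm = TRUE))
        bad <- c(bad, "gene and taxon ids must be positive integers")
    if (!nzchar(trimws(proposal$submitter)))
        bad <- c(bad, "submitter name required")
    else if (!is.null(registry) && !(proposal$submitter %in% registry))
        bad <- c(bad, sprintf("submitter '%s' is not registered",
                              proposal$submitter))
    ## taxon must agree with the gene table where the gene is annotated
    for (side in c("a", "b")) {
        g <- proposal[[paste0("gene_", side)]]
        t <- proposal[[paste0("tax_", side)]]
        known <- taxOf(g, kb)
        if (!is.na(g) && !is.na(known) && !is.na(t) && known != t)
            bad <- c(bad, sprintf("gene %d is annotated in taxon %d, not %d",
                                  g, known, t))
    }
    if (length(bad))
        return(structure(list(status = "invalid", matches = integer(0),
                              messages = bad), class = "SubmissionVerdict"))

    msgs <- c(msgs, sprintf("subject: %s (gene %d, taxon %d)",
                            symbolOf(proposal$gene_a, kb), proposal$gene_a,
                            proposal$tax_a),
              sprintf("object: %s (gene %d, taxon %d)",
                      symbolOf(proposal$gene_b, kb), proposal$gene_b,
                      proposal$tax_b),
              sprintf("PubMed ids: %s",
                      paste(proposal$pubmed_ids, collapse = ", ")))
    matches <- redundantRecords(proposal, kb@interactions)
    if (length(matches)) {
        msgs <- c(msgs, sprintf(
            "potential redundancy: record(s) %s already document this pair and type",
            paste(matches, collapse = ", ")))
        status <- "redundant_warning"
    } else {
        msgs <- c(msgs, "green light: no existing record matches this pair and type")
        status <- "green_light"
    }
    structure(list(status = status, matches = matches, messages = msgs),
              class = "SubmissionVerdict")
}

#' @export
print.SubmissionVerdict <- function(x, ...) {
    cat(sprintf("[%s]\n", x$status))
    for (m in x$messages) cat(" ", m, "\n")
    invisible(x)
}

#' Commit a proposed interaction to the knowledgebase
#'
#' Appends the proposal as a new user-submitted record with a fresh record
#' id and the submitter's name, and logs an `add` event in the history.
#' An invalid proposal is rejected outright; a redundant one is rejected
#' unless `force = TRUE` (a new citation for a known interaction may be
#' force-committed as additional documentation).
#'
#' @param kb a [Knowledgebase-class]
#' @param proposal a `SubmissionProposal`
#' @param force commit despite a redundancy warning
#' @param registry optional registered-submitter names (see
#'   [precheckSubmission()])
#' @param timestamp ISO-8601 text recorded in the history event; defaults
#'   to the current UTC time (pass a fixed value for reproducible output)
#' @return list with elements `kb` (the updated [Knowledgebase-class]) and
#'   `recordId` (the new record's id)
#' @export
commitSubmission <- function(kb, proposal, force = FALSE, registry = NULL,
                             timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                                tz = "UTC")) {
    verdict <- precheckSubmission(proposal, kb, registry)
    if (verdict$status == "invalid")
        nkbStop("netkb_usage_error", "invalid proposal: %s",
                paste(verdict$messages, collapse = "; "), data = verdict)
    if (verdict$status == "redundant_warning" && !force)
        nkbStop("netkb_usage_error",
                "proposal is redundant with record(s) %s; use force to commit anyway",
                paste(verdict$matches, collapse = ", "), data = verdict)
    newId <- if (nrow(kb@interactions)) max(kb@interactions$record_id) + 1L
             else 1L
    rec <- data.frame(
        record_id = newId, gene_a = proposal$gene_a, tax_a = proposal$tax_a,
        gene_b = proposal$gene_b, tax_b = proposal$tax_b,
        interaction_type = proposal$interaction_type,
        directed = proposal$interaction_type == "protein_dna",
        pubmed_ids = paste(proposal$pubmed_ids, collapse = ","),
        submitter = proposal$submitter,
        annotation_status = "user_submitted", stringsAsFactors = FALSE)
    nextSeq <- if (nrow(kb@history)) max(kb@history$sequence_no) + 1L else 1L
    ev <- data.frame(sequence_no = nextSeq, action = "add",
                     record_id = newId, user = proposal$submitter,
                     timestamp = timestamp, stringsAsFactors = FALSE)
    kb@interactions <- rbind(kb@interactions, rec)
    kb@history <- rbind(kb@history, ev)
    kb <- canonicalizeKb(kb)
    methods::validObject(kb)
    list(kb = kb, recordId = newId)
}

#' Revert the knowledgebase to an earlier history state
#'
#' Removes every user-submitted record whose `add` event has a sequence
#' number greater than `sequenceNo`, leaving the curated baseline
#' untouched. `sequenceNo = 0` reverts to the curated baseline. By default
#' the history is truncated to the target state, so reverting immediately
#' after a commit restores the previous serialization byte-for-byte; with
#' `log = TRUE` a `revert` event is appended instead, keeping an audit
#' trail at the cost of byte-identity.
#'
#' @param kb a [Knowledgebase-class]
#' @param sequenceNo target history sequence number (0 = curated baseline)
#' @param log append a `revert` ChangeEvent instead of truncating history
#' @param user,timestamp attribution for the logged event when `log = TRUE`
#' @return the reverted [Knowledgebase-class]
#' @export
revertTo <- function(kb, sequenceNo, log = FALSE, user = "system",
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                        tz = "UTC")) {
    hs <- kb@history
    if (sequenceNo != 0 && !(sequenceNo %in% hs$sequence_no))
        nkbStop("netkb_usage_error", "unknown history sequence number: %d",
                sequenceNo)
    undone <- hs$record_id[hs$action == "add" & hs$sequence_no > sequenceNo]
    keep <- !(kb@interactions$record_id %in% undone &
              kb@interactions$annotation_status == "user_submitted")
    kb@interactions <- kb@interactions[keep, , drop = FALSE]
    if (log) {
        nextSeq <- if (nrow(hs)) max(hs$sequence_no) + 1L else 1L
        kb@history <- rbind(hs, data.frame(
            sequence_no = nextSeq, action = "revert",
            record_id = as.integer(sequenceNo), user = user,
            timestamp = timestamp, stringsAsFactors = FALSE))
    } else {
        kb@history <- hs[hs$sequence_no <= sequenceNo, , drop = FALSE]
    }
    kb <- canonicalizeKb(kb)
    methods::validObject(kb)
    kb
}

#' Replay the change history over a curated baseline
#'
#' Reconstructs the interaction table by applying the history events of
#' `kb` in sequence order to the curated baseline: `add` events re-insert
#' the corresponding user-submitted record (looked up in `kb`'s interaction
#' table), `revert` events remove the user-submitted records added after
#' their target sequence number. Replaying a knowledgebase's own history
#' over its own curated records reproduces its interaction table exactly.
#'
#' @param kb a [Knowledgebase-class] whose history to replay
#' @param baseline optional [Knowledgebase-class] supplying the curated
#'   records; defaults to the curated subset of `kb`
#' @return a [Knowledgebase-class] with the replayed interaction table
#' @export
replayHistory <- function(kb, baseline = NULL) {
    if (is.null(baseline)) {
        baseline <- kb
        baseline@interactions <- kb@interactions[
            kb@interactions$annotation_status == "curated", , drop = FALSE]
        baseline@history <- emptyHistory()
    }
    pool <- kb@interactions  # record content addressed by record_id
    out <- baseline@interactions[
        baseline@interactions$annotation_status == "curated", , drop = FALSE]
    hs <- kb@history[order(kb@history$sequence_no), , drop = FALSE]
    added <- integer(0)  # record_id of each replayed add, in event order
    addedSeq <- integer(0)
    missing <- integer(0)  # adds whose content is gone (must be reverted later)
    for (i in seq_len(nrow(hs))) {
        if (hs$action[i] == "add") {
            rec <- pool[pool$record_id == hs$record_id[i], , drop = FALSE]
            if (nrow(rec) == 1)
                out <- rbind(out, rec)
            else  # content absent: only legal if a later revert undoes it
                missing <- c(missing, hs$record_id[i])
            added <- c(added, hs$record_id[i])
            addedSeq <- c(addedSeq, hs$sequence_no[i])
        } else {  # revert: record_id column carries the target sequence_no
            target <- hs$record_id[i]
            drop <- added[addedSeq > target]
            out <- out[!(out$record_id %in% drop &
                         out$annotation_status == "user_submitted"), ,
                       drop = FALSE]
            missing <- setdiff(missing, drop)
            added <- added[addedSeq <= target]
            addedSeq <- addedSeq[addedSeq <= target]
        }
    }
    if (length(missing))
        nkbStop("netkb_integrity_error",
                "history add event(s) reference unknown record(s): %s",
                paste(missing, collapse = ", "))
    res <- kb
    res@interactions <- out
    canonicalizeKb(res)
}
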