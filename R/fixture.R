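## Synthetic knowledgebase fixtures. Documented interaction corpora are
## scale-free: most genes have one or two documented partners while a few
## hubs have very many. The generator emulates that with preferential
## attachment, plus multiple taxa, cross-taxon ortholog groups and a mixed
## bag of interaction types, so the whole engine is testable offline.

TAXON_POOL <- c(9606L, 10090L, 10116L, 7227L, 7955L, 6239L, 4932L, 511145L)

GO_VOCAB <- c("cardiac muscle development", "bone remodeling",
              "alcohol metabolism", "transcription regulation",
              "signal transduction", "cell cycle", "apoptosis",
              "chromatin organization", "immune response", "lipid transport")

DESC_VOCAB <- c("transcription factor", "kinase", "phosphatase",
                "structural protein", "membrane receptor", "transporter",
                "chaperone", "ubiquitin ligase", "RNA binding protein",
                "uncharacterized protein")

DEFAULT_TYPE_MIX <- c(protein_protein = 0.60, protein_dna = 0.20,
                      genetic = 0.15, other = 0.05)

randomPubmed <- function(n) {
    vapply(seq_len(n), function(i) {
        k <- sample(1:2, 1)
        paste(sample.int(2e7, k) + 10000000L, collapse = ",")
    }, "")
}

#' Generate a seeded synthetic knowledgebase
#'
#' Builds a self-contained [Knowledgebase-class] whose interaction graph has
#' preferential-attachment (scale-free) degree structure: each new
#' interaction picks its endpoints with probability proportional to current
#' degree + 1, producing a few hubs and many low-degree genes. Genes are
#' spread over `nTaxa` taxa; a fraction of them is organized into
#' cross-taxon ortholog groups of size 2-3; interaction types are drawn from
#' `typeMix`. The same seed always yields a byte-identical knowledgebase
#' when serialized.
#'
#' @param nGenes number of genes (>= 2)
#' @param nTaxa number of taxa (1-8), drawn from a fixed pool of NCBI-style
#'   taxon ids starting with human/mouse/rat
#' @param nInteractions number of interaction records (>= 0)
#' @param orthologFraction fraction of genes placed into ortholog groups
#' @param typeMix named weights over the four interaction types
#' @param seed integer RNG seed; the generator is a pure function of its
#'   arguments
#' @param userFraction fraction of records marked user_submitted (tagged
#'   with a synthetic submitter name)
#' @return a [Knowledgebase-class]
#' @examples
#' kb <- generateFixture(50, 3, 120, seed = 7)
#' kb
#' @export
generateFixture <- function(nGenes, nTaxa = 3, nInteractions = 2 * nGenes,
                            orthologFraction = 0.3,
                            typeMix = DEFAULT_TYPE_MIX, seed,
                            userFraction = 0) {
    if (nGenes < 2)
        nkbStop("netkb_usage_error", "nGenes must be >= 2")
    if (nInteractions < 0)
        nkbStop("netkb_usage_error", "nInteractions must be >= 0")
    if (nTaxa < 1 || nTaxa > length(TAXON_POOL))
        nkbStop("netkb_usage_error", "nTaxa must be between 1 and %d",
                length(TAXON_POOL))
    mix <- rep(0, length(INTERACTION_TYPES))
    names(mix) <- INTERACTION_TYPES
    mix[names(typeMix)] <- typeMix
    if (sum(mix) <= 0 || any(mix < 0))
        nkbStop("netkb_usage_error", "typeMix weights must be non-negative and sum > 0")

    withSeed(seed, {
        taxa <- TAXON_POOL[seq_len(nTaxa)]
        geneIds <- 1000L + seq_len(nGenes)
        taxOfGene <- sample(taxa, nGenes, replace = TRUE)
        gn <- data.frame(
            gene_id = geneIds, tax_id = taxOfGene,
            symbol = sprintf("GENE%d", seq_len(nGenes)),
            synonyms = vapply(seq_len(nGenes), function(i) {
                k <- sample(0:2, 1)
                if (k == 0) "" else
                    paste(sprintf("SYN%d%s", i, letters[seq_len(k)]),
                          collapse = "|")
            }, ""),
            description = sample(DESC_VOCAB, nGenes, replace = TRUE),
            go_terms = vapply(seq_len(nGenes), function(i)
                paste(sample(GO_VOCAB, sample(1:3, 1)), collapse = "|"), ""),
            stringsAsFactors = FALSE)

        ## ortholog groups of size 2-3 over a shuffled subset of the genes
        hm <- emptyHomology()
        nOrth <- floor(orthologFraction * nGenes)
        if (nOrth >= 2) {
            pool <- sample(seq_len(nGenes), nOrth)
            hid <- 0L
            rows <- list()
            while (length(pool) >= 2) {
                sz <- min(length(pool), sample(2:3, 1))
                hid <- hid + 1L
                take <- pool[seq_len(sz)]
                pool <- pool[-seq_len(sz)]
                rows[[hid]] <- data.frame(homologene_id = 100L + hid,
                                          gene_id = geneIds[take],
                                          tax_id = taxOfGene[take])
            }
            hm <- do.call(rbind, rows)
        }

        ix <- emptyInteractions()
        if (nInteractions > 0) {
            deg <- rep(0, nGenes)
            a <- integer(nInteractions); b <- integer(nInteractions)
            for (k in seq_len(nInteractions)) {
                i <- sample.int(nGenes, 1, prob = deg + 1)
                j <- sample.int(nGenes, 1, prob = deg + 1)
                if (i == j)  # allow rare self-loops, but retry once
                    j <- sample.int(nGenes, 1, prob = deg + 1)
                a[k] <- i; b[k] <- j
                deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1
            }
            types <- sample(INTERACTION_TYPES, nInteractions, replace = TRUE,
                            prob = mix)
            isUser <- stats::runif(nInteractions) < userFraction
            ix <- data.frame(
                record_id = seq_len(nInteractions),
                gene_a = geneIds[a], tax_a = taxOfGene[a],
                gene_b = geneIds[b], tax_b = taxOfGene[b],
                interaction_type = types,
                directed = types == "protein_dna",
                pubmed_ids = randomPubmed(nInteractions),
                submitter = ifelse(isUser,
                                   sprintf("user%d", sample(1:5, nInteractions,
                                                            replace = TRUE)),
                                   ""),
                annotation_status = ifelse(isUser, "user_submitted", "curated"),
                stringsAsFactors = FALSE)
        }
        canonicalizeKb(methods::new("Knowledgebase", interactions = ix,
                                    genes = gn, homology = hm,
                                    history = emptyHistory()))
    })
}

#' Generate a complexity-demonstration fixture with cross-taxon hubs
#'
#' Builds a knowledgebase shaped like the pluripotency-factor worked example:
#' a small set of hub genes, each present as a full ortholog group across
#' all taxa, each hub surrounded by mostly-private documented partners in
#' every taxon, plus a few partners shared between hubs (the intermediates)
#' and background interactions away from the hubs. Querying the hubs in two
#' overlapping groups then demonstrates the two complexity dials: network
#' radius and single-organism confinement.
#'
#' @param seed integer RNG seed
#' @param nTaxa number of taxa for the ortholog groups (default 3)
#' @param nHubs number of hub genes (default 6; queried as two groups of 4
#'   overlapping in hubs 3 and 4)
#' @param meanNeighbors mean number of private partners per hub per taxon
#' @param nShared number of shared partners (intermediates) per taxon
#' @param nBackground number of background genes with hub-free interactions
#' @return a list with elements `kb` (a [Knowledgebase-class]),
#'   `queryString` (two '/'-separated groups of hub symbols overlapping in
#'   two genes), `resolutionTaxon` (taxon used to resolve the symbols) and
#'   `singleTaxon` (taxon for single-organism runs)
#' @export
generateComplexityFixture <- function(seed, nTaxa = 3, nHubs = 6,
                                      meanNeighbors = 8, nShared = 4,
                                      nBackground = 30) {
    stopifnot(nHubs >= 4, nTaxa >= 2)
    withSeed(seed, {
        taxa <- TAXON_POOL[seq_len(nTaxa)]
        nextId <- 1000L
        newIds <- function(n) {
            ids <- nextId + seq_len(n)
            nextId <<- as.integer(nextId + n)
            ids
        }
        genes <- list(); homs <- list(); edges <- list()
        addGene <- function(id, tax, sym) {
            genes[[length(genes) + 1L]] <<- data.frame(
                gene_id = id, tax_id = tax, symbol = sym, synonyms = "",
                description = sample(DESC_VOCAB, 1),
                go_terms = sample(GO_VOCAB, 1), stringsAsFactors = FALSE)
        }
        addEdge <- function(ga, ta, gb, tb) {
            type <- sample(INTERACTION_TYPES, 1,
                           prob = DEFAULT_TYPE_MIX[INTERACTION_TYPES])
            edges[[length(edges) + 1L]] <<- data.frame(
                gene_a = ga, tax_a = ta, gene_b = gb, tax_b = tb,
                interaction_type = type, directed = type == "protein_dna",
                stringsAsFactors = FALSE)
        }

        ## hubs: one ortholog per taxon, same symbol in each taxon
        hub <- matrix(0L, nrow = nHubs, ncol = nTaxa)
        for (j in seq_len(nHubs)) {
            ids <- newIds(nTaxa)
            hub[j, ] <- ids
            for (t in seq_len(nTaxa))
                addGene(ids[t], taxa[t], sprintf("HUB%d", j))
            homs[[j]] <- data.frame(homologene_id = 500L + j, gene_id = ids,
                                    tax_id = taxa)
        }
        ## private partners: each hub ortholog gets its own neighbors
        for (j in seq_len(nHubs)) for (t in seq_len(nTaxa)) {
            k <- stats::rpois(1, meanNeighbors) + 1L
            ids <- newIds(k)
            for (i in seq_len(k)) {
                addGene(ids[i], taxa[t], sprintf("P%d", ids[i]))
                addEdge(hub[j, t], taxa[t], ids[i], taxa[t])
            }
        }
        ## shared partners: linked to >= 2 hubs of the same taxon, so they
        ## qualify as intermediates for the hub query
        for (t in seq_len(nTaxa)) {
            ids <- newIds(nShared)
            for (i in seq_len(nShared)) {
                addGene(ids[i], taxa[t], sprintf("S%d", ids[i]))
                for (j in sample(seq_len(nHubs), sample(2:3, 1)))
                    addEdge(ids[i], taxa[t], hub[j, t], taxa[t])
            }
        }
        ## background genes interacting among themselves only
        if (nBackground >= 2) {
            ids <- newIds(nBackground)
            bgTax <- sample(taxa, nBackground, replace = TRUE)
            for (i in seq_len(nBackground))
                addGene(ids[i], bgTax[i], sprintf("B%d", ids[i]))
            for (k in seq_len(nBackground)) {
                ii <- sample(nBackground, 2)
                addEdge(ids[ii[1]], bgTax[ii[1]], ids[ii[2]], bgTax[ii[2]])
            }
        }

        ed <- do.call(rbind, edges)
        ix <- data.frame(record_id = seq_len(nrow(ed)), ed,
                         pubmed_ids = randomPubmed(nrow(ed)),
                         submitter = "", annotation_status = "curated",
                         stringsAsFactors = FALSE)
        ix <- ix[, names(emptyInteractions())]
        kb <- canonicalizeKb(methods::new("Knowledgebase",
            interactions = ix, genes = do.call(rbind, genes),
            homology = do.call(rbind, homs), history = emptyHistory()))
        g1 <- paste(sprintf("HUB%d", 1:4), collapse = ", ")
        g2 <- paste(sprintf("HUB%d", 3:nHubs), collapse = ", ")
        list(kb = kb, queryString = paste(g1, g2, sep = "/"),
             resolutionTaxon = taxa[1], singleTaxon = taxa[1])
    })
}
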