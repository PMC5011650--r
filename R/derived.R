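## Frequency-of-occurrence tally shared by CGS and URG/DRG selection:
## for every gene, the number of signatures (among `signatures`) in whose
## leading edge it appears in at least one of the profiled datasets.
## With countPairs = TRUE, signature x dataset incidences are counted
## instead of distinct signatures.
leadingEdgeFrequency <- function(signatures, profiles, countPairs = FALSE) {
    counts <- integer(0)
    for (sig in signatures) {
        seen <- character(0)
        for (pr in profiles) {
            le <- leadingEdges(pr)[[sig]]
            if (is.null(le)) next
            if (countPairs) {
                counts[le] <- ifelse(is.na(counts[le]), 0L, counts[le]) + 1L
            } else {
                seen <- union(seen, le)
            }
        }
        if (!countPairs && length(seen))
            counts[seen] <- ifelse(is.na(counts[seen]), 0L,
                                   counts[seen]) + 1L
    }
    counts
}

## Top-fraction selection on a positive-frequency tally: take the
## ceil(topFrac * #genes) highest-frequency genes, keeping every tie at the
## cutoff frequency (frequencies are small integers, so strict truncation
## would be order-dependent).
selectTopFrequency <- function(freq, topFrac) {
    if (!length(freq)) return(freq)
    o <- orderDescWithNames(freq, names(freq))
    nTake <- ceiling(topFrac * length(freq))
    cutoff <- freq[o][nTake]
    freq[freq >= cutoff]
}

#' Extract a cluster gene set (CGS)
#'
#' For a cluster of signatures, genes are tallied by frequency of
#' occurrence: the number of cluster signatures in whose GSEA leading edge
#' (against at least one dataset) the gene appears.  The genes with the
#' highest `topFrac` (default 5%) of the positive-frequency distribution
#' are selected, including all ties at the cutoff frequency.
#'
#' @param clusterSignatures character vector of the cluster's signature
#'   names; must be non-empty.
#' @param profiles list of GSEA [EnrichmentProfile-class] objects (one per
#'   dataset) carrying leading edges.
#' @param topFrac selected fraction (default 0.05).
#' @param label label for the derived set.
#' @param countPairs count signature x dataset incidences instead of
#'   distinct signatures.
#' @return A [DerivedGeneSet-class].
#' @export
extractCgs <- function(clusterSignatures, profiles, topFrac = 0.05,
                       label = "CGS", countPairs = FALSE) {
    if (!length(clusterSignatures)) stop("empty signature cluster")
    freq <- leadingEdgeFrequency(clusterSignatures, profiles, countPairs)
    sel <- selectTopFrequency(freq, topFrac)
    new("DerivedGeneSet", label = label, genes = names(sel),
        frequency = as.integer(sel) |> setNames(names(sel)),
        signatures = as.character(clusterSignatures))
}

#' Consistent-signature sets (PNS/NNS) for a genotype
#'
#' Steps (b)-(d) of the URG/DRG procedure: over the genotype's datasets,
#' each signature's -log10 nominal p values are aggregated (sum by default;
#' `aggregate = "product"` multiplies them), the top `topFrac` of all N
#' signatures — exactly `floor(topFrac * N)`, boundary ties broken by
#' signature name — are kept, and split into the positive-NES set (PNS:
#' NES > 0 in every dataset) and negative-NES set (NNS: NES < 0 in every
#' dataset).  Mixed-sign signatures belong to neither.
#'
#' @param profiles list of GSEA [EnrichmentProfile-class] objects for the
#'   genotype's datasets only.
#' @param topFrac selected fraction of signatures (default 0.05).
#' @param aggregate `"sum"` or `"product"` of the per-dataset -log10 p.
#' @return list of class `SignatureConsistencySets`: `pns`, `nns` (character
#'   vectors), `table` (signature, aggregated -log p, allPositive,
#'   allNegative, selected).
#' @export
signatureConsistencySets <- function(profiles, topFrac = 0.05,
                                     aggregate = c("sum", "product")) {
    aggregate <- match.arg(aggregate)
    stopifnot(length(profiles) > 0)
    sigs <- enrichmentTable(profiles[[1]])$signature
    nlp <- matrix(NA_real_, length(sigs), length(profiles),
                  dimnames = list(sigs, NULL))
    nes <- nlp
    for (j in seq_along(profiles)) {
        tab <- enrichmentTable(profiles[[j]])
        nlp[tab$signature, j] <- -log10(tab$pNominal)
        nes[tab$signature, j] <- tab$nes
    }
    complete <- !apply(nlp, 1L, anyNA) & !apply(nes, 1L, anyNA)
    if (any(!complete))
        message(sum(!complete),
                " signature(s) excluded: missing NES/p in some dataset")
    score <- if (aggregate == "sum") rowSums(nlp) else
        apply(nlp, 1L, prod)
    N <- length(sigs)
    nTop <- floor(topFrac * N)
    score[!complete] <- -Inf
    o <- orderDescWithNames(score, sigs)
    top <- sigs[o][seq_len(min(nTop, sum(complete)))]
    allPos <- apply(nes > 0, 1L, all)
    allNeg <- apply(nes < 0, 1L, all)
    out <- list(pns = top[allPos[top] %in% TRUE],
                nns = top[allNeg[top] %in% TRUE],
                table = data.frame(signature = sigs,
                                   aggregatedNegLogP = score,
                                   allPositive = allPos,
                                   allNegative = allNeg,
                                   selected = sigs %in% top,
                                   row.names = NULL,
                                   stringsAsFactors = FALSE))
    class(out) <- "SignatureConsistencySets"
    out
}

#' Select URG and DRG sets for a genotype
#'
#' Steps (e)-(g): leading-edge genes of every PNS signature against every
#' dataset of the genotype are collected and ranked by frequency of
#' occurrence in PNS; the top `topFrac` (with ties at the cutoff, as in
#' [extractCgs()]) form the up-regulated gene set (URG).  The same applied
#' to NNS yields the down-regulated set (DRG).
#'
#' @param consistency a `SignatureConsistencySets` from
#'   [signatureConsistencySets()].
#' @param profiles the genotype's GSEA [EnrichmentProfile-class] objects.
#' @param topFrac selected fraction (default 0.05).
#' @param label genotype label used to name the derived sets.
#' @return list with `urg` and `drg`, both [DerivedGeneSet-class] (empty
#'   when PNS/NNS is empty, with a warning).
#' @export
selectUrgDrg <- function(consistency, profiles, topFrac = 0.05,
                         label = "T") {
    mk <- function(sigs, tag) {
        if (!length(sigs)) {
            warning("empty ", tag, " for ", label,
                    ": returning an empty gene set")
            return(new("DerivedGeneSet",
                       label = paste0(tag, "-", label),
                       genes = character(0),
                       frequency = integer(0), signatures = character(0)))
        }
        extractCgs(sigs, profiles, topFrac = topFrac,
                   label = paste0(tag, "-", label))
    }
    list(urg = mk(consistency$pns, "URG"),
         drg = mk(consistency$nns, "DRG"))
}
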