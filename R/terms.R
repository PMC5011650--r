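#' Fisher exact over-representation of a gene set in functional terms
#'
#' One-sided Fisher exact test (hypergeometric upper tail) of the 2x2 table
#' in-query/in-term versus their complements within the universe, for every
#' term in the collection; BH adjustment across terms.  Query genes outside
#' the universe are dropped with a warning; term sets are intersected with
#' the universe.
#'
#' @param query character vector of gene symbols (e.g. a derived gene set).
#' @param terms a [SignatureSet-class] of GO/KEGG-style terms.
#' @param universe character vector of all assayable gene symbols; must be
#'   non-empty.
#' @return data.frame with columns `term`, `overlap`, `termSize`,
#'   `querySize`, `universeSize`, `pValue`, `negLogP` (-log10 p), `fdr`.
#' @examples
#' terms <- SignatureSet(list(T1 = c("a", "b", "c")))
#' fisherEnrichment(c("a", "b"), terms, universe = letters[1:10])
#' @export
fisherEnrichment <- function(query, terms, universe) {
    stopifnot(is(terms, "SignatureSet"))
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty universe")
    query <- unique(as.character(query))
    outside <- setdiff(query, universe)
    if (length(outside)) {
        warning("dropping ", length(outside),
                " query gene(s) outside the universe")
        query <- intersect(query, universe)
    }
    N <- length(universe); n <- length(query)
    res <- lapply(names(terms), function(nm) {
        term <- intersect(terms[[nm]], universe)
        K <- length(term)
        k <- length(intersect(term, query))
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(term = nm, overlap = k, termSize = K, querySize = n,
                   universeSize = N, pValue = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$negLogP <- -log10(out$pValue)
    out$fdr <- stats::p.adjust(out$pValue, method = "BH")
    out
}

#' Side-by-side -log10 p matrix of term enrichments
#'
#' Assembles the functional readout comparing several derived gene sets
#' over a shared subset of terms.
#'
#' @param results named list of data.frames from [fisherEnrichment()] (one
#'   per derived set).
#' @param termSubset character vector of term names shared by all results
#'   (defaults to the first result's terms).
#' @return matrix (derived sets x terms) of -log10 p values.
#' @export
compareEnrichmentProfiles <- function(results, termSubset = NULL) {
    stopifnot(length(results) > 0, !is.null(names(results)))
    if (is.null(termSubset)) termSubset <- results[[1]]$term
    M <- do.call(rbind, lapply(results, function(df) {
        setNames(df$negLogP, df$term)[termSubset]
    }))
    rownames(M) <- names(results)
    colnames(M) <- termSubset
    M
}
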