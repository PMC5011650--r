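#' Size-filter signatures by overlap with every dataset's gene universe
#'
#' A signature is retained iff its overlap with EVERY universe (platform
#' gene list) lies within `[minN, maxN]`, inclusive at both ends — the
#' standard "not less than 10 and not greater than 200 overlapping genes
#' across all platforms" rule.
#'
#' @param collection a [SignatureSet-class].
#' @param universes list of character vectors of gene symbols (one per
#'   dataset/platform).
#' @param minN,maxN inclusive overlap bounds (defaults 10 and 200).
#' @return The filtered [SignatureSet-class].
#' @export
filterSignaturesByOverlap <- function(collection, universes,
                                      minN = 10, maxN = 200) {
    stopifnot(is(collection, "SignatureSet"), length(universes) > 0)
    keep <- vapply(names(collection), function(nm) {
        g <- collection[[nm]]
        all(vapply(universes, function(u) {
            o <- length(intersect(g, u))
            o >= minN && o <= maxN
        }, logical(1)))
    }, logical(1))
    collection[which(keep)]
}

#' Select signatures by nominal-p recurrence across datasets
#'
#' A signature is selected iff its nominal p is below `pMax` in at least
#' `minDatasets` of the profiled datasets (the "p < 0.05 in not less than
#' 10 of the 18 datasets" rule).
#'
#' @param profiles list of [EnrichmentProfile-class] objects over a shared
#'   collection.
#' @param pMax nominal p threshold (strict `<`).
#' @param minDatasets minimum number of qualifying datasets (inclusive).
#' @return character vector of selected signature names, in collection
#'   order.
#' @export
selectSignaturesGsea <- function(profiles, pMax = 0.05, minDatasets = 10) {
    counts <- signatureHitCounts(profiles, "pNominal", pMax)
    names(counts)[counts >= minDatasets]
}

#' Select signatures by per-dataset FDR
#'
#' Per-dataset Benjamini-Hochberg FDR; a signature is selected when its FDR
#' is below `fdrMax` (strict) in at least `minDatasets` datasets.
#'
#' @param profiles list of [EnrichmentProfile-class] objects.
#' @param fdrMax FDR threshold (strict `<`).
#' @param minDatasets minimum number of qualifying datasets (default 1).
#' @return character vector of selected signature names.
#' @export
selectSignaturesByFdr <- function(profiles, fdrMax, minDatasets = 1) {
    counts <- signatureHitCounts(profiles, "fdr", fdrMax)
    names(counts)[counts >= minDatasets]
}

signatureHitCounts <- function(profiles, column, threshold) {
    stopifnot(length(profiles) > 0)
    sigs <- enrichmentTable(profiles[[1]])$signature
    counts <- setNames(integer(length(sigs)), sigs)
    for (pr in profiles) {
        tab <- enrichmentTable(pr)
        if (!setequal(tab$signature, sigs))
            stop("profiles must cover the same signature collection")
        v <- setNames(tab[[column]], tab$signature)[sigs]
        hit <- !is.na(v) & v < threshold
        counts <- counts + hit
    }
    counts
}

#' Select the highest-variance genes across datasets
#'
#' Sample variance of each gene's log2 ratio across datasets; the top `k`
#' genes by variance are returned, ties broken lexicographically.
#'
#' @param lrMatrix genes x datasets matrix of log2 ratios (genes present in
#'   all datasets).
#' @param k number of genes to keep (default 152).
#' @return character vector of k gene symbols.
#' @export
selectHighVarianceGenes <- function(lrMatrix, k = 152) {
    stopifnot(is.matrix(lrMatrix), !is.null(rownames(lrMatrix)))
    if (k > nrow(lrMatrix))
        stop("k exceeds the number of available genes")
    v <- apply(lrMatrix, 1L, stats::var)
    rownames(lrMatrix)[orderDescWithNames(v, rownames(lrMatrix))][seq_len(k)]
}

#' Assemble a datasets x features profile matrix
#'
#' Rows are datasets, columns the selected features: NES values when
#' `mode = "nes"` (from [EnrichmentProfile-class] objects) or log2 ratios
#' when `mode = "log2_ratio"` (from [computeContrast()] tables).  Features
#' undefined (NA) in any dataset are dropped with a warning.
#'
#' @param features character vector of selected feature names (signatures
#'   or genes); must be non-empty.
#' @param source named list: per-dataset [EnrichmentProfile-class] objects
#'   (`mode = "nes"`) or per-dataset data.frames from [computeContrast()]
#'   (`mode = "log2_ratio"`).
#' @param mode `"nes"` or `"log2_ratio"`.
#' @return numeric matrix (datasets x features) with a `"mode"` attribute.
#' @export
buildProfile <- function(features, source, mode = c("nes", "log2_ratio")) {
    mode <- match.arg(mode)
    if (!length(features)) stop("empty feature list")
    if (is.null(names(source))) stop("'source' must be a named list")
    rows <- lapply(source, function(x) {
        if (mode == "nes") {
            tab <- enrichmentTable(x)
            v <- setNames(tab$nes, tab$signature)
        } else {
            v <- setNames(x$log2Ratio, x$gene)
        }
        v[features]
    })
    M <- do.call(rbind, rows)
    rownames(M) <- names(source)
    colnames(M) <- features
    bad <- apply(M, 2L, anyNA)
    if (any(bad)) {
        warning("dropping feature(s) undefined in some dataset: ",
                paste(features[bad], collapse = ", "))
        M <- M[, !bad, drop = FALSE]
    }
    if (!ncol(M)) stop("no feature is defined in every dataset")
    attr(M, "mode") <- mode
    M
}
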