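#' Pairwise Pearson correlation matrix of profile vectors
#'
#' Correlates the rows (datasets) or columns (features) of a profile
#' matrix.  Constant vectors, whose correlation is undefined, are excluded
#' with a warning.
#'
#' @param profile numeric matrix (datasets x features).
#' @param axis `"rows"` or `"cols"`.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearsonMatrix <- function(profile, axis = c("rows", "cols")) {
    axis <- match.arg(axis)
    x <- if (axis == "rows") t(profile) else profile
    if (nrow(x) < 2) stop("need >= 2 features per vector")
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
        warning("excluding constant vector(s): ",
                paste(colnames(x)[sds == 0], collapse = ", "))
        x <- x[, sds > 0, drop = FALSE]
    }
    r <- stats::cor(x)
    diag(r) <- 1
    r
}

#' Agglomerative clustering with Pearson distance
#'
#' Hierarchical clustering with distance `1 - r` (anticorrelated profiles
#' are maximally distant) and the given linkage, cut into `k` clusters.
#' Accepts either a symmetric correlation matrix (unit diagonal) or a raw
#' profile matrix, whose rows are then correlated first.
#'
#' @param x correlation matrix or profile matrix.
#' @param k number of clusters (`k <=` number of items).
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`, i.e. UPGMA).
#' @return list with `labels` (named integer cluster labels), `order`
#'   (dendrogram leaf order), `hclust` (the tree), `correlation`.
#' @export
hierarchicalCluster <- function(x, k, linkage = "average") {
    r <- if (isSymmetric(unname(x)) &&
             isTRUE(all.equal(unname(diag(x)), rep(1, nrow(x)))))
        x else pearsonMatrix(x, "rows")
    if (k > nrow(r)) stop("k exceeds the number of items")
    if (nrow(r) == 1L)    # a single item forms its own (only) cluster
        return(list(labels = stats::setNames(1L, rownames(r)),
                    order = 1L, hclust = NULL, correlation = r))
    hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
    labels <- stats::cutree(hc, k = k)
    list(labels = labels, order = hc$order, hclust = hc, correlation = r)
}

#' Two-way hierarchical clustering of a profile matrix
#'
#' Applies [hierarchicalCluster()] independently to the rows (datasets,
#' yielding the genotype grouping) and the columns (features) of a profile
#' matrix; the reordered matrix plus labels form the heatmap export.
#'
#' @param profile datasets x features matrix from [buildProfile()].
#' @param kRows,kCols numbers of dataset and feature clusters (default 3
#'   and 3).
#' @param linkage linkage method.
#' @return A [GenotypeAssignment-class].
#' @export
twoWayCluster <- function(profile, kRows = 3, kCols = 3,
                          linkage = "average") {
    rowCl <- hierarchicalCluster(pearsonMatrix(profile, "rows"), kRows,
                                 linkage)
    colCl <- hierarchicalCluster(pearsonMatrix(profile, "cols"), kCols,
                                 linkage)
    new("GenotypeAssignment",
        datasetClusters = rowCl$labels,
        featureClusters = colCl$labels,
        datasetOrder = as.integer(rowCl$order),
        featureOrder = as.integer(colCl$order),
        datasetCor = rowCl$correlation,
        profile = profile)
}

#' Classify datasets with a small collection of known signatures
#'
#' The two-way clustering machinery applied to the NES profile of a small
#' curated collection (e.g. six known cancer/stem-cell signatures).
#' All-NA or constant NES columns are excluded with a warning.
#'
#' @param profiles named list of [EnrichmentProfile-class] objects computed
#'   against the known collection.
#' @param kRows dataset cluster count (default 2: the over-/under-expressed
#'   split).
#' @param kCols feature cluster count (default 2).
#' @param linkage linkage method.
#' @return A [GenotypeAssignment-class].
#' @export
classifyKnownSignatures <- function(profiles, kRows = 2, kCols = 2,
                                    linkage = "average") {
    sigs <- enrichmentTable(profiles[[1]])$signature
    M <- buildProfile(sigs, profiles, mode = "nes")
    sds <- apply(M, 2L, stats::sd)
    if (any(sds == 0)) {
        warning("excluding constant NES column(s): ",
                paste(colnames(M)[sds == 0], collapse = ", "))
        M <- M[, sds > 0, drop = FALSE]
    }
    twoWayCluster(M, kRows = kRows, kCols = min(kCols, ncol(M)),
                  linkage = linkage)
}

#' Export a clustering dendrogram as newick text
#'
#' @param hc an `hclust` object (e.g. from [hierarchicalCluster()]).
#' @return single newick string.
#' @export
dendrogramNewick <- function(hc) {
    ape::write.tree(ape::as.phylo(hc))
}
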