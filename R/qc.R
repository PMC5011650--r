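#' PCA separation score of a matched contrast
#'
#' Quality metric for a test-vs-control dataset: genes are centered, the
#' samples' principal components computed, and for each of the first
#' `nAxes` components every threshold between consecutive projected values
#' (and both group-to-side assignments) is scanned for the split that
#' minimizes the number of misplaced samples.  The score is
#' `1 - minMisplaced / nSamples`, so a cleanly separated dataset scores 1
#' and the score never falls below 0.5 (the empty split misplaces at most
#' the smaller arm).
#'
#' @param dataset a [ContrastExperiment-class] with at least 2 samples per
#'   arm and 2 genes.
#' @param nAxes number of leading principal components scanned (default 2).
#'   Ties in misplaced count resolve toward the lower axis index.
#' @return list of class `SeparationReport`: `pcaScore`, `nMisplaced`,
#'   `axisUsed`, `threshold`, `nSamples`.
#' @export
pcaSeparationScore <- function(dataset, nAxes = 2) {
    m <- log2ExprMatrix(dataset)
    if (nrow(m) < 2) stop("need at least 2 genes")
    if (length(controlSamples(dataset)) < 2 ||
        length(testSamples(dataset)) < 2)
        stop("need at least 2 samples per arm")
    if (all(apply(m, 1L, stats::var) == 0))
        stop("degenerate matrix: zero total variance")
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    nAxes <- min(nAxes, ncol(pc$x))
    isCtl <- colnames(m) %in% controlSamples(dataset)
    n <- ncol(m)
    best <- list(mis = n + 1L, axis = NA_integer_, thr = NA_real_)
    for (a in seq_len(nAxes)) {
        sp <- bestSplit1d(pc$x[, a], isCtl)
        if (sp$mis < best$mis)
            best <- list(mis = sp$mis, axis = a, thr = sp$thr)
    }
    structure(list(pcaScore = 1 - best$mis / n,
                   nMisplaced = as.integer(best$mis),
                   axisUsed = best$axis,
                   threshold = best$thr,
                   nSamples = n),
              class = "SeparationReport")
}

## Best single-threshold bipartition of projected values: scan all n+1 cut
## points (midpoints between consecutive sorted values, plus the two outer
## cuts) under both group-to-side assignments.
bestSplit1d <- function(x, isCtl) {
    o <- order(x)
    xs <- x[o]; cs <- isCtl[o]
    n <- length(x)
    cumCtl <- c(0, cumsum(cs))        # controls in the left block of size i
    cumTst <- c(0, cumsum(!cs))
    totCtl <- cumCtl[n + 1]; totTst <- cumTst[n + 1]
    ## assignment A: control left of threshold; B: test left
    misA <- (totCtl - cumCtl[1:(n + 1)]) + cumTst[1:(n + 1)]
    misB <- (totTst - cumTst[1:(n + 1)]) + cumCtl[1:(n + 1)]
    mis <- pmin(misA, misB)
    i <- which.min(mis)               # first minimum: lowest cut wins ties
    thr <- if (i == 1) xs[1] - 1
           else if (i == n + 1) xs[n] + 1
           else (xs[i - 1] + xs[i]) / 2
    list(mis = mis[i], thr = thr)
}

#' Gate datasets on their PCA separation score
#'
#' @param reports named list of `SeparationReport` objects (one per dataset).
#' @param minScore acceptance threshold, inclusive (default 0.75).
#' @return list with character vectors `accepted` and `rejected`.
#' @export
gateDatasets <- function(reports, minScore = 0.75) {
    if (!length(reports))
        return(list(accepted = character(0), rejected = character(0)))
    if (is.null(names(reports)))
        stop("'reports' must be a named list")
    ok <- vapply(reports, function(r) r$pcaScore >= minScore, logical(1))
    list(accepted = names(reports)[ok], rejected = names(reports)[!ok])
}
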