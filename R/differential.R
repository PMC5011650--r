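#' Per-gene contrast statistics (the individual-gene approach)
#'
#' For every gene: log2 ratio (mean test minus mean control), pooled-variance
#' two-sample Student t with `n1 + n2 - 2` degrees of freedom, two-sided p,
#' and Benjamini-Hochberg adjusted FDR over all genes.  Genes with zero
#' pooled variance get `p = 1` when their log2 ratio is 0; otherwise their
#' variance is floored at the smallest positive pooled variance observed.
#'
#' @param dataset a [ContrastExperiment-class] with >= 2 samples per arm.
#' @param moderated if `TRUE`, an empirical-Bayes moderated t
#'   (via \pkg{limma}) replaces the plain Student t.
#' @param fdrMax,fcMin thresholds used for the convenience `isDeg` flag
#'   (strict inequalities, FDR < `fdrMax` and fold change > `fcMin`).
#' @return data.frame with columns `gene`, `log2Ratio`, `t`, `pValue`,
#'   `fdr`, `isDeg`.
#' @export
computeContrast <- function(dataset, moderated = FALSE,
                            fdrMax = 0.05, fcMin = 2) {
    m <- log2ExprMatrix(dataset)
    ctl <- controlSamples(dataset); tst <- testSamples(dataset)
    if (length(ctl) < 2 || length(tst) < 2)
        stop("need >= 2 samples per arm; use a fold-change-only comparison ",
             "for single-sample arms")
    mC <- m[, ctl, drop = FALSE]; mT <- m[, tst, drop = FALSE]
    n1 <- ncol(mC); n2 <- ncol(mT)
    lr <- rowMeans(mT) - rowMeans(mC)
    if (moderated) {
        design <- cbind(Intercept = 1,
                        test = as.numeric(colnames(m) %in% tst))
        fit <- limma::eBayes(limma::lmFit(m, design))
        tstat <- fit$t[, "test"]
        p <- fit$p.value[, "test"]
    } else {
        v1 <- apply(mC, 1L, stats::var)
        v2 <- apply(mT, 1L, stats::var)
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        zero <- sp2 == 0
        if (any(zero)) {
            floorVar <- suppressWarnings(min(sp2[!zero]))
            if (!is.finite(floorVar)) floorVar <- .Machine$double.eps
            sp2[zero & lr != 0] <- floorVar
        }
        se <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
        tstat <- ifelse(se > 0, lr / se, 0)
        p <- 2 * stats::pt(-abs(tstat), df)
        p[sp2 == 0 & lr == 0] <- 1
    }
    fdr <- stats::p.adjust(p, method = "BH")
    data.frame(gene = rownames(m), log2Ratio = lr, t = tstat,
               pValue = p, fdr = fdr,
               isDeg = fdr < fdrMax & 2^abs(lr) > fcMin,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Select differentially expressed genes
#'
#' A gene is selected iff `fdr < fdrMax` and `2^|log2Ratio| > fcMin`
#' (both strict, matching the conventional "FDR < 0.05, FC > 2" rule).
#'
#' @param result a data.frame from [computeContrast()].
#' @param fdrMax,fcMin positive thresholds.
#' @return character vector of selected gene symbols.
#' @export
selectDegs <- function(result, fdrMax = 0.05, fcMin = 2) {
    stopifnot(fdrMax > 0, fcMin > 0)
    result$gene[result$fdr < fdrMax & 2^abs(result$log2Ratio) > fcMin]
}

#' Pairwise DEG overlap matrix
#'
#' `M[i, j] = |D_i intersect D_j| / |D_i|` (the denominator is always the
#' row set), so the matrix is asymmetric and satisfies
#' `M[i, j] * |D_i| = |D_i intersect D_j|`.  Diagonal entries are 1.
#' Rows/columns of empty DEG sets are reported as `NA` and flagged in the
#' `"undefined"` attribute rather than set to zero.
#'
#' @param degSets named list of character vectors (per-dataset DEG sets).
#' @return numeric matrix with an `"undefined"` attribute naming datasets
#'   with empty sets.
#' @export
degOverlapMatrix <- function(degSets) {
    if (is.null(names(degSets))) stop("'degSets' must be named")
    n <- length(degSets)
    M <- matrix(NA_real_, n, n, dimnames = list(names(degSets),
                                                names(degSets)))
    empty <- names(degSets)[lengths(degSets) == 0L]
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (length(degSets[[i]]) && length(degSets[[j]]))
            M[i, j] <- length(intersect(degSets[[i]], degSets[[j]])) /
                length(degSets[[i]])
    }
    diag(M)[!rownames(M) %in% empty] <- 1
    attr(M, "undefined") <- empty
    M
}
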