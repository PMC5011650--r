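## Shared fixtures and independent oracles.

# Minimal ContrastExperiment from a matrix (first nCtl columns = control).
makeDataset <- function(m, nCtl, name = "fix") {
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    ContrastExperiment(m, controlIds = colnames(m)[seq_len(nCtl)],
                       testIds = colnames(m)[(nCtl + 1):ncol(m)],
                       name = name)
}

# Small default simulation used across tests.
smallSimConfig <- function(seed, ...) {
    args <- list(nGenes = 500, delta = 1.5, nControl = 6, nTest = 6,
                 noiseSd = 0.5,
                 modules = c(proliferation = 30L, emt = 30L,
                             glia_marker = 20L, breast_marker = 20L,
                             secretory_marker = 20L),
                 nDecoySignatures = 10, seed = seed)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(simulationConfig, args)
}

# Brute-force running-sum oracle: explicit position-by-position walk,
# independent of the package's closed-form hit-position evaluation.
bruteEs <- function(ranked, signature, weight = 1) {
    N <- length(ranked)
    hits <- names(ranked) %in% signature
    m <- sum(hits)
    w <- abs(ranked)^weight
    denom <- sum(w[hits])
    if (denom == 0) { w[] <- 1; denom <- m }
    dev <- numeric(N)
    phit <- 0; pmiss <- 0
    for (i in seq_len(N)) {
        if (hits[i]) phit <- phit + w[i] / denom
        else pmiss <- pmiss + 1 / (N - m)
        dev[i] <- phit - pmiss
    }
    maxd <- max(dev); mind <- min(dev)
    base <- list(maxDev = maxd, minDev = mind,
                 finalHit = unname(phit), finalMiss = pmiss)
    if (maxd >= -mind)
        c(list(es = maxd, peakIndex = which.max(dev)), base)
    else
        c(list(es = mind, peakIndex = which.min(dev)), base)
}

# Exhaustive PCA-split oracle: every axis, every threshold position, both
# group-to-side assignments.
brutePcaScore <- function(dataset, nAxes = 2) {
    m <- SummarizedExperiment::assay(dataset, "log2expr")
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    isCtl <- colnames(m) %in% controlSamples(dataset)
    n <- ncol(m)
    best <- n + 1
    for (a in seq_len(min(nAxes, ncol(pc$x)))) {
        x <- pc$x[, a]
        for (i in 0:n) {
            left <- rank(x, ties.method = "first") <= i
            misA <- sum(isCtl & !left) + sum(!isCtl & left)
            misB <- sum(!isCtl & !left) + sum(isCtl & left)
            best <- min(best, misA, misB)
        }
    }
    1 - best / n
}

# Hypergeometric upper-tail oracle by direct enumeration of the 2x2 tables.
bruteHyperP <- function(k, K, N, n) {
    kk <- k:min(K, n)
    sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
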