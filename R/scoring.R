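#' Rank genes by a contrast metric
#'
#' Default metric is signal-to-noise:
#' `(mean_test - mean_control) / (sd_test + sd_control)`, with each arm's
#' standard deviation floored at `max(0.2 * |arm mean|, 0.2)`.  The
#' alternative `"log2_ratio"` metric is the plain difference of arm means.
#' Genes are ordered by the metric, descending; ties break by gene symbol
#' (lexicographic, C locale) so the ordering is total and deterministic.
#'
#' @param dataset a [ContrastExperiment-class] (>= 2 samples per arm for
#'   signal-to-noise).
#' @param metric `"signal_to_noise"` or `"log2_ratio"`.
#' @return named numeric vector of metric values, in ranking order.
#' @export
rankGenes <- function(dataset, metric = c("signal_to_noise", "log2_ratio")) {
    metric <- match.arg(metric)
    m <- log2ExprMatrix(dataset)
    ctl <- controlSamples(dataset); tst <- testSamples(dataset)
    if (!length(ctl) || !length(tst)) stop("both arms must be non-empty")
    mC <- m[, ctl, drop = FALSE]; mT <- m[, tst, drop = FALSE]
    muC <- rowMeans(mC); muT <- rowMeans(mT)
    if (metric == "signal_to_noise") {
        if (ncol(mC) < 2 || ncol(mT) < 2)
            stop("signal-to-noise needs >= 2 samples per arm")
        sdC <- pmax(apply(mC, 1L, stats::sd), 0.2 * abs(muC), 0.2)
        sdT <- pmax(apply(mT, 1L, stats::sd), 0.2 * abs(muT), 0.2)
        r <- (muT - muC) / (sdT + sdC)
    } else {
        r <- muT - muC
    }
    r[orderDescWithNames(r, names(r))]
}

## Weighted running-sum enrichment score from sorted hit positions.
## wAll: |metric|^weight over the full ranking; pos: sorted signature
## positions.  The walk's maxima sit at hit positions, its minima just
## before hit positions, so only 2m points need evaluating.
esFromPositions <- function(wAll, N, pos) {
    m <- length(pos)
    hitw <- wAll[pos]
    s <- sum(hitw)
    if (s == 0) { hitw <- rep(1, m); s <- m }      # degenerate zero weights
    cumhit <- cumsum(hitw) / s
    missAt <- (pos - seq_len(m)) / (N - m)         # P_miss just before hit i
    up <- cumhit - missAt                          # deviation at hit i
    down <- c(0, cumhit[-m]) - missAt              # deviation before hit i
    maxUp <- max(up); minDown <- min(down)
    if (maxUp >= -minDown)
        list(es = maxUp, peakIndex = pos[which.max(up)])
    else
        list(es = minDown, peakIndex = pos[which.min(down)] - 1L)
}

#' GSEA running-sum enrichment score
#'
#' Walks the ranking: at signature genes the hit mass increments by
#' `|r_i|^weight / sum(|r_g|^weight over the signature)`, at other genes the
#' miss mass increments by `1 / (N - m)`.  The enrichment score is the signed
#' maximum deviation of (hit - miss); `peakIndex` is the first position
#' attaining it.
#'
#' @param ranked named metric vector from [rankGenes()].
#' @param signature character vector of gene symbols; its overlap m with the
#'   ranking must satisfy `1 <= m < N`.
#' @param weight exponent on the metric magnitudes (GSEA's p; default 1).
#' @return list with `es`, `peakIndex`, `m`.
#' @examples
#' r <- c(a = 4, b = 3, c = 2, d = 1)
#' enrichmentScore(r, c("a", "c"))$es  # 2/3
#' @export
enrichmentScore <- function(ranked, signature, weight = 1) {
    N <- length(ranked)
    pos <- which(names(ranked) %in% signature)
    m <- length(pos)
    if (m == 0) stop("signature has no overlap with the ranking")
    if (m == N) stop("signature covers the entire ranking")
    w <- abs(ranked)^weight
    out <- esFromPositions(w, N, pos)
    out$m <- m
    out
}

#' Permutation normalization and nominal p for an enrichment score
#'
#' Gene-permutation null: `nPerm` random same-size gene sets are scored on
#' the same ranking.  `nes = es / |mean(permuted es of the same sign)|`
#' (sign preserved) and
#' `p = (1 + #extreme same-sign) / (1 + #same-sign)` (add-one rule, never 0).
#' When no permuted score shares the sign of `es`, NES is undefined and
#' flagged.
#'
#' @param es observed enrichment score.
#' @param ranked named metric vector from [rankGenes()].
#' @param signature gene set scored.
#' @param nPerm number of permutations (>= 10).
#' @param weight exponent on metric magnitudes.
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @return list with `nes`, `pNominal`, `flag` (`"ok"` or
#'   `"nes_undefined"`).
#' @export
normalizeAndTest <- function(es, ranked, signature, nPerm = 1000,
                             weight = 1, seed = NULL) {
    stopifnot(nPerm >= 10)
    N <- length(ranked)
    m <- sum(names(ranked) %in% signature)
    if (m == 0 || m == N) stop("invalid signature overlap")
    w <- abs(ranked)^weight
    perm <- withSeed(seed, permutedEs(w, N, m, nPerm))
    same <- perm[sign(perm) == sign(es)]
    if (!length(same))
        return(list(nes = NA_real_, pNominal = NA_real_,
                    flag = "nes_undefined"))
    list(nes = es / abs(mean(same)),
         pNominal = (1 + sum(abs(same) >= abs(es))) / (1 + length(same)),
         flag = "ok")
}

permutedEs <- function(w, N, m, nPerm) {
    vapply(seq_len(nPerm), function(i) {
        esFromPositions(w, N, sort.int(sample.int(N, m)))$es
    }, numeric(1))
}

#' Leading-edge genes of an enrichment score
#'
#' For positive es, the signature genes at ranking positions at or before
#' the running-sum peak; for negative es, those at or after it.
#'
#' @param ranked named metric vector.
#' @param signature gene set.
#' @param es,peakIndex from [enrichmentScore()]; `es` must be non-zero.
#' @return character vector of leading-edge genes.
#' @export
leadingEdge <- function(ranked, signature, es, peakIndex) {
    if (es == 0) stop("leading edge undefined for es = 0")
    pos <- which(names(ranked) %in% signature)
    keep <- if (es > 0) pos <= peakIndex else pos >= peakIndex
    names(ranked)[pos[keep]]
}

#' PAGE z-score for a gene set
#'
#' Parametric gene-set statistic: with `mu` and `delta` the mean and sample
#' standard deviation of all gene-level values and `Sm` the signature mean
#' over its m overlapping genes, `z = (Sm - mu) * sqrt(m) / delta`, with a
#' two-sided standard-normal p.
#'
#' @param log2Ratios named per-gene values (typically log2 ratios).
#' @param signature gene set (overlap m >= 1 required).
#' @return list with `z`, `p`, `m`.
#' @export
pageZscore <- function(log2Ratios, signature) {
    ov <- intersect(names(log2Ratios), signature)
    m <- length(ov)
    if (m < 1) stop("signature has no overlap with the gene values")
    mu <- mean(log2Ratios)
    delta <- stats::sd(log2Ratios)
    if (!is.finite(delta) || delta == 0)
        stop("degenerate contrast: zero dispersion of gene-level values")
    z <- (mean(log2Ratios[ov]) - mu) * sqrt(m) / delta
    list(z = z, p = 2 * stats::pnorm(-abs(z)), m = m)
}

#' Pairwise GAGE-style gene-set score
#'
#' For every (test, control) sample pair, per-gene log2 fold changes are
#' formed and the signature genes compared to all genes by a two-sample
#' Welch t test; the pairwise one-sided p values are combined by Stouffer's
#' method into a single z and a two-sided combined p.
#'
#' @param dataset a [ContrastExperiment-class].
#' @param signature gene set (overlap m >= 2 required).
#' @return list with `stat` (combined z), `p`, `m`, or flag `"skipped"`
#'   when the overlap is below 2.
#' @export
gageScore <- function(dataset, signature) {
    m <- log2ExprMatrix(dataset)
    ov <- intersect(rownames(m), signature)
    if (length(ov) < 2)
        return(list(stat = NA_real_, p = NA_real_, m = length(ov),
                    flag = "skipped"))
    ctl <- controlSamples(dataset); tst <- testSamples(dataset)
    zs <- c()
    for (s in tst) for (cc in ctl) {
        fc <- m[, s] - m[, cc]
        tt <- stats::t.test(fc[ov], fc)
        p1 <- unname(stats::pt(tt$statistic, tt$parameter,
                               lower.tail = FALSE))
        zs <- c(zs, stats::qnorm(1 - p1))
    }
    z <- sum(zs) / sqrt(length(zs))
    list(stat = z, p = 2 * stats::pnorm(-abs(z)), m = length(ov),
         flag = "ok")
}

#' Profile a dataset against a signature collection
#'
#' One enrichment record per signature using the chosen method; signatures
#' that cannot be scored (no overlap, full overlap, undefined NES) are kept
#' with NA statistics and a non-`"ok"` flag, never aborting the profile.
#' FDR is Benjamini-Hochberg across the scored signatures' nominal p values.
#'
#' @param dataset a [ContrastExperiment-class].
#' @param collection a [SignatureSet-class], already size-filtered
#'   (see [filterSignaturesByOverlap()]).
#' @param method `"gsea"`, `"page"` or `"gage"`.
#' @param nPerm GSEA permutation count.
#' @param weight GSEA metric exponent.
#' @param metric ranking metric, see [rankGenes()].
#' @param seed RNG seed governing the permutation null.
#' @return An [EnrichmentProfile-class].
#' @export
profileDataset <- function(dataset, collection,
                           method = c("gsea", "page", "gage"),
                           nPerm = 1000, weight = 1,
                           metric = "signal_to_noise", seed = 1) {
    method <- match.arg(method)
    stopifnot(is(collection, "SignatureSet"))
    nms <- names(collection)
    n <- length(collection)
    res <- data.frame(signature = if (n) nms else character(0),
                      m = integer(n), es = rep(NA_real_, n),
                      nes = rep(NA_real_, n), pNominal = rep(NA_real_, n),
                      fdr = rep(NA_real_, n),
                      flag = rep("ok", n), stringsAsFactors = FALSE)
    le <- list()
    if (n) {
        if (method == "gsea") {
            ranked <- rankGenes(dataset, metric = metric)
            N <- length(ranked)
            withSeed(seed, for (i in seq_len(n)) {
                ov <- sum(names(ranked) %in% collection[[i]])
                res$m[i] <- ov
                if (ov == 0 || ov == N) {
                    res$flag[i] <- if (ov == 0) "no_overlap" else
                        "full_overlap"
                    next
                }
                sc <- enrichmentScore(ranked, collection[[i]], weight)
                nt <- normalizeAndTest(sc$es, ranked, collection[[i]],
                                       nPerm = nPerm, weight = weight)
                res$es[i] <- sc$es
                res$nes[i] <- nt$nes
                res$pNominal[i] <- nt$pNominal
                res$flag[i] <- nt$flag
                if (sc$es != 0)
                    le[[nms[i]]] <- leadingEdge(ranked, collection[[i]],
                                                sc$es, sc$peakIndex)
            })
        } else if (method == "page") {
            lr <- rankGenes(dataset, metric = "log2_ratio")
            for (i in seq_len(n)) {
                ov <- intersect(names(lr), collection[[i]])
                res$m[i] <- length(ov)
                if (!length(ov)) { res$flag[i] <- "no_overlap"; next }
                pz <- pageZscore(lr, collection[[i]])
                res$es[i] <- pz$z; res$nes[i] <- pz$z
                res$pNominal[i] <- pz$p
            }
        } else {
            for (i in seq_len(n)) {
                gs <- gageScore(dataset, collection[[i]])
                res$m[i] <- gs$m
                if (gs$flag != "ok") { res$flag[i] <- gs$flag; next }
                res$es[i] <- gs$stat; res$nes[i] <- gs$stat
                res$pNominal[i] <- gs$p
            }
        }
        ok <- res$flag == "ok" & !is.na(res$pNominal)
        res$fdr[ok] <- stats::p.adjust(res$pNominal[ok], method = "BH")
    }
    new("EnrichmentProfile", dataset = datasetName(dataset),
        method = method, results = res, leadingEdges = le)
}
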