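test_that("gene ranking applies the signal-to-noise formula with sd floor", {
    m <- rbind(up = c(1, 1.2, 0.8, 3, 3.3, 2.7),
               dn = c(4, 4.1, 3.9, 2, 2.2, 1.8),
               nil = c(1, 1.1, 0.9, 1.0, 1.05, 0.95))
    colnames(m) <- paste0("s", 1:6)
    d <- makeDataset(m, 3)
    r <- rankGenes(d)
    # hand evaluation with each sd floored at max(0.2|mean|, 0.2)
    s2n <- function(x) {
        mC <- mean(x[1:3]); mT <- mean(x[4:6])
        sC <- max(sd(x[1:3]), 0.2 * abs(mC), 0.2)
        sT <- max(sd(x[4:6]), 0.2 * abs(mT), 0.2)
        (mT - mC) / (sT + sC)
    }
    expected <- apply(m, 1L, s2n)
    expect_equal(r, expected[names(r)], tolerance = 1e-12)
    expect_identical(names(r)[1], "up")
    expect_identical(names(r)[3], "dn")
})

test_that("ranking ties break lexicographically and order is descending", {
    m <- rbind(zeb = c(1, 1, 2, 2), ant = c(1, 1, 2, 2),
               top = c(0, 0, 9, 9))
    colnames(m) <- paste0("s", 1:4)
    r <- rankGenes(makeDataset(m, 2))
    expect_identical(names(r), c("top", "ant", "zeb"))
})

test_that("running-sum enrichment score reproduces the worked example", {
    r <- c(a = 4, b = 3, c = 2, d = 1)
    sc <- enrichmentScore(r, c("a", "c"))
    expect_equal(sc$es, 2 / 3)
    expect_equal(sc$peakIndex, 1L)
    expect_identical(leadingEdge(r, c("a", "c"), sc$es, sc$peakIndex), "a")
    # top-loaded signature: hit mass reaches 1 before any miss
    expect_equal(enrichmentScore(r, c("a", "b"))$es, 1)
    # bottom-loaded mirror: negative es, leading edge in the tail
    scN <- enrichmentScore(r, c("c", "d"))
    expect_lt(scN$es, 0)
    expect_setequal(leadingEdge(r, c("c", "d"), scN$es, scN$peakIndex),
                    c("c", "d"))
})

test_that("enrichment score matches brute-force recomputation on fixtures", {
    set.seed(99)
    for (i in 1:100) {
        N <- sample(5:50, 1)
        genes <- sprintf("g%02d", seq_len(N))
        r <- setNames(sort(rnorm(N), decreasing = TRUE), sample(genes))
        m <- sample(1:(N - 1), 1)
        sig <- sample(genes, m)
        w <- sample(c(0, 1), 1)
        got <- enrichmentScore(r, sig, weight = w)
        want <- bruteEs(r, sig, weight = w)
        if (abs(want$maxDev + want$minDev) < 1e-9) {
            # |max| and |min| deviations tie to rounding: the signed choice
            # is not numerically stable, so compare magnitudes only
            expect_equal(abs(got$es), abs(want$es), tolerance = 1e-12,
                         info = paste("fixture", i))
        } else {
            expect_equal(got$es, want$es, tolerance = 1e-12,
                         info = paste("fixture", i))
            expect_equal(got$peakIndex, want$peakIndex,
                         info = paste("fixture", i))
        }
        expect_gte(got$es, -1); expect_lte(got$es, 1)
        # total hit and miss mass each reach 1 at the end of the walk
        expect_equal(want$finalHit, 1, tolerance = 1e-12)
        expect_equal(want$finalMiss, 1, tolerance = 1e-12)
    }
})

test_that("enrichment score agrees with an independent GSEA implementation", {
    skip_if_not_installed("fgsea")
    set.seed(5)
    for (i in 1:10) {
        N <- 40
        r <- setNames(sort(rnorm(N), decreasing = TRUE),
                      sprintf("g%02d", 1:N))
        sig <- sample(names(r), 8)
        ours <- enrichmentScore(r, sig, weight = 1)$es
        theirs <- fgsea::calcGseaStat(r, which(names(r) %in% sig),
                                      gseaParam = 1)
        expect_equal(ours, theirs, tolerance = 1e-12)
    }
})

test_that("reversing the ranking negates the unweighted score", {
    set.seed(12)
    r <- setNames(seq(2, -2, length.out = 20), sprintf("g%02d", 1:20))
    sig <- sample(names(r), 6)
    es1 <- enrichmentScore(r, sig, weight = 0)$es
    rev <- r[rev(names(r))]
    # evaluate on the reversed ordering (metric values irrelevant at p=0)
    es2 <- enrichmentScore(setNames(seq(2, -2, length.out = 20),
                                    names(rev)), sig, weight = 0)$es
    expect_equal(es2, -es1, tolerance = 1e-12)
})

test_that("permutation normalization follows the add-one convention", {
    # weight 0, single-gene signature at the top: every same-sign permuted
    # score equals the observed score exactly
    r <- setNames(c(5, 1), c("hi", "lo"))
    sc <- enrichmentScore(r, "hi", weight = 0)
    nt <- normalizeAndTest(sc$es, r, "hi", nPerm = 50, weight = 0, seed = 4)
    expect_equal(nt$nes, 1)
    expect_equal(nt$pNominal, 1)

    # observed score beating every positive permuted score: p = 1/(k+1)
    set.seed(2)
    r2 <- setNames(sort(rnorm(30), decreasing = TRUE),
                   sprintf("g%02d", 1:30))
    sig <- names(r2)[1:5]          # top-loaded, es = 1 unbeatable
    sc2 <- enrichmentScore(r2, sig)
    nt2 <- normalizeAndTest(sc2$es, r2, sig, nPerm = 200, seed = 9)
    perm <- withr::with_seed(9, cscmeta:::permutedEs(abs(r2), 30, 5, 200))
    k <- sum(perm > 0 & abs(perm) >= 1)  # ties at 1 count as extreme
    expect_equal(nt2$pNominal,
                 (1 + k) / (1 + sum(sign(perm) == 1)))
    expect_equal(sign(nt2$nes), sign(sc2$es))
    # deterministic given the seed
    nt3 <- normalizeAndTest(sc2$es, r2, sig, nPerm = 200, seed = 9)
    expect_identical(nt2, nt3)
})

test_that("PAGE z-score matches its closed form", {
    expect_equal(pageZscore(c(g1 = 1, g2 = 2, g3 = 3, g4 = 4),
                            c("g4", "g3"))$z,
                 sqrt(2) / sqrt(5 / 3), tolerance = 1e-12)
    flat <- pageZscore(c(a = 1, b = 2, c = 3), c("a", "c"))
    expect_equal(flat$z, 0)
    expect_equal(flat$p, 1)
    expect_error(pageZscore(c(a = 1, b = 1), "a"), "zero dispersion")
})

test_that("GAGE pairwise score behaves at its degenerate points", {
    set.seed(14)
    m <- matrix(rnorm(50 * 4, 5), 50, 4)
    d <- makeDataset(m, 2)
    sig <- rownames(SummarizedExperiment::assay(d))[1:10]
    # single (test, control) pair: combined p equals that pair's p
    one <- makeDataset(m[, c(1, 3), drop = FALSE], 1)
    fc <- SummarizedExperiment::assay(one)[, 2] -
        SummarizedExperiment::assay(one)[, 1]
    genes <- names(fc)[1:10]
    gs <- gageScore(one, genes)
    tt <- stats::t.test(fc[genes], fc)
    p1 <- stats::pt(tt$statistic, tt$parameter, lower.tail = FALSE)
    expect_equal(gs$p,
                 unname(2 * stats::pnorm(-abs(stats::qnorm(1 - p1)))),
                 tolerance = 1e-10)
    # no signal: combined p stays large
    g0 <- gageScore(d, sig)
    expect_gt(g0$p, 0.05)
    # overlap below 2 is skipped, not an error
    expect_identical(gageScore(d, "g001")$flag, "skipped")
})

test_that("a planted up-module is detected by the GAGE score", {
    cfg <- smallSimConfig(3, nGenes = 400, delta = 2, nControl = 3,
                          nTest = 3,
                          modules = c(proliferation = 30L),
                          genotypes = list(
                              T1 = list(nDatasets = 1L,
                                        effects = c(proliferation = 2))),
                          nDecoySignatures = 0)
    sim <- simulateCollection(cfg)
    g <- gageScore(sim$datasets[[1]], sim$truth$modules$proliferation)
    expect_lt(g$p, 1e-3)
})

test_that("dataset profiling is deterministic and finds planted modules", {
    cfg <- smallSimConfig(6, delta = 3, noiseSd = 0.25)
    sim <- simulateCollection(cfg)
    d <- sim$datasets[["T1_ds1"]]
    pr1 <- profileDataset(d, sim$signatures, nPerm = 100, seed = 11)
    pr2 <- profileDataset(d, sim$signatures, nPerm = 100, seed = 11)
    expect_identical(enrichmentTable(pr1), enrichmentTable(pr2))
    expect_identical(leadingEdges(pr1), leadingEdges(pr2))
    tab <- enrichmentTable(pr1)
    top <- tab$signature[which.max(abs(tab$nes))]
    expect_true(top %in% c("MOD_PROLIFERATION", "MOD_EMT",
                           "MOD_GLIA_MARKER"))
    # empty collection gives an empty profile
    empty <- profileDataset(d, SignatureSet(), nPerm = 100)
    expect_equal(nrow(enrichmentTable(empty)), 0)
    # leading edges restricted to signature overlap
    for (nm in names(leadingEdges(pr1)))
        expect_true(all(leadingEdges(pr1)[[nm]] %in%
                        sim$signatures[[nm]]))
})
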