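test_that("Pearson matrix matches the covariance formula", {
    set.seed(3)
    M <- matrix(rnorm(4 * 8), 4, 8,
                dimnames = list(paste0("d", 1:4), paste0("f", 1:8)))
    r <- pearsonMatrix(M, "rows")
    oracle <- function(x, y) {
        n <- length(x)
        num <- sum((x - mean(x)) * (y - mean(y)))
        num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    }
    for (i in 1:4) for (j in 1:4) {
        want <- if (i == j) 1 else oracle(M[i, ], M[j, ])
        expect_equal(r[i, j], want, tolerance = 1e-12)
    }
    M2 <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(-1, -2, -3))
    r2 <- pearsonMatrix(M2, "rows")
    expect_equal(r2["a", "b"], 1)
    expect_equal(r2["a", "c"], -1)
    # constant vectors are excluded with a warning
    M3 <- rbind(a = c(1, 2, 3), flat = c(5, 5, 5), b = c(3, 1, 2))
    expect_warning(r3 <- pearsonMatrix(M3, "rows"), "flat")
    expect_identical(rownames(r3), c("a", "b"))
})

test_that("hierarchical clustering recovers planted correlation blocks", {
    set.seed(41)
    base <- matrix(rnorm(3 * 30), 3, 30)
    M <- base[rep(1:3, each = 4), ] + matrix(rnorm(12 * 30, 0, 0.1), 12, 30)
    rownames(M) <- sprintf("d%02d", 1:12)
    cl <- hierarchicalCluster(pearsonMatrix(M, "rows"), k = 3)
    expect_equal(ari(cl$labels, rep(1:3, each = 4)), 1.0)
    # identical items merge first at distance 0
    M2 <- rbind(a = c(1, 2, 3, 1), b = c(1, 2, 3, 1), c = c(9, 1, 4, 2))
    cl2 <- hierarchicalCluster(pearsonMatrix(M2, "rows"), k = 2)
    expect_equal(cl2$hclust$height[1], 0, tolerance = 1e-12)
    expect_equal(cl2$labels[["a"]], cl2$labels[["b"]])
    # k = number of items yields singletons
    cl3 <- hierarchicalCluster(pearsonMatrix(M2, "rows"), k = 3)
    expect_equal(length(unique(cl3$labels)), 3)
    expect_error(hierarchicalCluster(pearsonMatrix(M2, "rows"), k = 4),
                 "exceeds")
})

test_that("two-way clustering is symmetric under transposition", {
    set.seed(19)
    M <- matrix(rnorm(6 * 9), 6, 9,
                dimnames = list(paste0("d", 1:6), paste0("f", 1:9)))
    ga <- twoWayCluster(M, kRows = 2, kCols = 3)
    gaT <- twoWayCluster(t(M), kRows = 3, kCols = 2)
    expect_identical(datasetClusters(ga), featureClusters(gaT))
    expect_identical(featureClusters(ga), datasetClusters(gaT))
    # single feature column: all features form one cluster
    fc1 <- hierarchicalCluster(pearsonMatrix(M[, 1, drop = FALSE], "cols"),
                               k = 1)
    expect_equal(unname(fc1$labels), 1L)
})

test_that("clustering is invariant to input permutation (up to relabel)", {
    set.seed(57)
    base <- matrix(rnorm(3 * 25), 3, 25)
    M <- base[rep(1:3, each = 3), ] + matrix(rnorm(9 * 25, 0, 0.1), 9, 25)
    rownames(M) <- sprintf("d%d", 1:9)
    colnames(M) <- sprintf("f%d", 1:25)
    ga <- twoWayCluster(M, kRows = 3, kCols = 3)
    perm <- sample(rownames(M))
    gaP <- twoWayCluster(M[perm, ], kRows = 3, kCols = 3)
    common <- rownames(M)
    expect_equal(ari(datasetClusters(ga)[common],
                     datasetClusters(gaP)[common]), 1.0)
})

test_that("planted genotypes are recovered from signature profiles", {
    sim <- simulateCollection(smallSimConfig(101))
    profs <- lapply(sim$datasets, profileDataset, sim$signatures,
                    nPerm = 100, seed = 5)
    sel <- selectSignaturesGsea(profs, pMax = 0.05, minDatasets = 3)
    expect_true(all(c("MOD_PROLIFERATION", "MOD_EMT") %in% sel))
    M <- buildProfile(sel, profs, mode = "nes")
    ga <- twoWayCluster(M, kRows = 3, kCols = min(3, ncol(M)))
    truth <- sim$truth$datasetGenotype[names(datasetClusters(ga))]
    expect_equal(ari(datasetClusters(ga), truth), 1.0)
})

test_that("known-signature classification separates module directions", {
    sim <- simulateCollection(smallSimConfig(67, delta = 2))
    known <- SignatureSet(c(geneSets(sim$signatures)[
        c("MOD_PROLIFERATION", "MOD_EMT")],
        geneSets(sim$signatures)[grep("DECOY", names(sim$signatures))[1:4]]))
    profs <- lapply(sim$datasets, profileDataset, known,
                    nPerm = 100, seed = 8)
    # decoy columns with an undefined NES in some dataset are dropped
    ga <- suppressWarnings(classifyKnownSignatures(profs, kRows = 2))
    lab <- datasetClusters(ga)
    # T1 (prolif up, EMT down) separates from T2 (EMT up)
    t1 <- lab[grep("^T1", names(lab))]
    t2 <- lab[grep("^T2", names(lab))]
    expect_equal(length(unique(t1)), 1)
    expect_equal(length(unique(t2)), 1)
    expect_false(unique(t1) == unique(t2))
})

test_that("dendrogram export produces parseable newick", {
    M <- matrix(rnorm(5 * 10), 5, 10,
                dimnames = list(paste0("d", 1:5), NULL))
    cl <- hierarchicalCluster(pearsonMatrix(M, "rows"), k = 2)
    nwk <- dendrogramNewick(cl$hclust)
    tree <- ape::read.tree(text = nwk)
    expect_setequal(tree$tip.label, paste0("d", 1:5))
})
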