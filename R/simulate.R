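#' Simulation configuration for synthetic CSC-style dataset collections
#'
#' Defines the study conditions emulated by [simulateCollection()]: several
#' matched contrasts per genotype, small sample arms, planted directional gene
#' modules with genotype-specific signed effects on the test arm, Gaussian
#' noise on log2 expression, and a signature collection containing the planted
#' modules among random decoys.
#'
#' The default genotype structure mirrors the proliferation/EMT dichotomy of
#' CSC genotypes: `T1` has proliferation up and EMT down, `T2` has EMT up,
#' `T3` has both down.  Each genotype additionally carries one up-regulated
#' tissue-marker module of its own, the analogue of the tissue-specific
#' signatures that distinguish real CSC datasets; without such markers a
#' Pearson-distance clustering over only two informative signature columns
#' is geometrically degenerate.
#'
#' @param nGenes number of genes on the simulated platform.
#' @param delta planted effect size in log2 units (default 1.5 = 3 x
#'   `noiseSd`, the reference recovery condition).
#' @param genotypes named list; each element is `list(nDatasets =, effects =)`
#'   where `effects` is a named numeric vector of signed log2 effects applied
#'   to test samples of the named modules.
#' @param nControl,nTest samples per arm of every dataset.
#' @param noiseSd Gaussian noise standard deviation, log2 units.
#' @param baselineMean,baselineSd per-gene baseline distribution, log2 units.
#' @param modules named integer vector: module name -> gene count; modules
#'   are disjoint gene sets.
#' @param nDecoySignatures number of random decoy signatures drawn uniformly
#'   from non-module genes.
#' @param signatureSizeRange integer length-2 vector of decoy signature sizes.
#' @param seed master RNG seed; per-dataset sub-seeds are derived by indexed
#'   offset.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenes = 2000,
                             delta = 1.5,
                             genotypes = NULL,
                             nControl = 6, nTest = 6,
                             noiseSd = 0.5,
                             baselineMean = 7, baselineSd = 1,
                             modules = c(proliferation = 50L, emt = 50L,
                                         glia_marker = 40L,
                                         breast_marker = 40L,
                                         secretory_marker = 40L),
                             nDecoySignatures = 50,
                             signatureSizeRange = c(20L, 100L),
                             seed = 1) {
    if (is.null(genotypes))
        genotypes <- list(
            T1 = list(nDatasets = 3L,
                      effects = c(proliferation = delta, emt = -delta,
                                  glia_marker = delta)),
            T2 = list(nDatasets = 3L,
                      effects = c(emt = delta, breast_marker = delta)),
            T3 = list(nDatasets = 3L,
                      effects = c(proliferation = -delta, emt = -delta,
                                  secretory_marker = delta)))
    cfg <- list(nGenes = as.integer(nGenes), delta = delta,
                genotypes = genotypes,
                nControl = as.integer(nControl), nTest = as.integer(nTest),
                noiseSd = noiseSd, baselineMean = baselineMean,
                baselineSd = baselineSd, modules = modules,
                nDecoySignatures = as.integer(nDecoySignatures),
                signatureSizeRange = as.integer(signatureSizeRange),
                seed = as.integer(seed))
    class(cfg) <- "SimulationConfig"
    validateSimulationConfig(cfg)
    cfg
}

validateSimulationConfig <- function(cfg) {
    with(cfg, {
        if (nGenes < 1 || nControl < 1 || nTest < 1 || nDecoySignatures < 0)
            stop("all counts must be positive")
        if (sum(modules) > nGenes)
            stop("module sizes exceed the number of genes")
        if (noiseSd < 0 || baselineSd < 0)
            stop("standard deviations must be non-negative")
        if (length(signatureSizeRange) != 2 ||
            signatureSizeRange[1] < 1 || signatureSizeRange[2] > nGenes ||
            signatureSizeRange[1] > signatureSizeRange[2])
            stop("signatureSizeRange must lie within [1, nGenes]")
        for (g in genotypes) {
            if (g$nDatasets < 1) stop("each genotype needs >= 1 dataset")
            bad <- setdiff(names(g$effects), names(modules))
            if (length(bad))
                stop("genotype effect names must be modules: ",
                     paste(bad, collapse = ", "))
        }
    })
    invisible(cfg)
}

#' Generate a synthetic multi-dataset collection with planted genotypes
#'
#' Per gene g and sample s, expression is
#' `baseline_g + delta_m * [g in module m and s in test arm] + noise`, with
#' `baseline_g ~ N(baselineMean, baselineSd)` drawn once per collection and
#' `noise ~ N(0, noiseSd)` drawn independently per cell.  The signature
#' collection holds one signature per planted module (named `MOD_<module>`)
#' plus decoy signatures drawn uniformly from non-module genes.  Fully
#' reproducible from `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return list with elements `datasets` (named list of
#'   [ContrastExperiment-class]), `signatures` (a [SignatureSet-class]), and
#'   `truth` (list with `datasetGenotype`, `modules`, `effects`).
#' @examples
#' cfg <- simulationConfig(nGenes = 300, nControl = 3, nTest = 3,
#'                         modules = c(proliferation = 20L, emt = 20L,
#'                                     glia_marker = 10L, breast_marker = 10L,
#'                                     secretory_marker = 10L),
#'                         nDecoySignatures = 5, seed = 7)
#' sim <- simulateCollection(cfg)
#' names(sim$datasets)
#' @export
simulateCollection <- function(config) {
    validateSimulationConfig(config)
    withSeed(config$seed, {
        genes <- sprintf("G%05d", seq_len(config$nGenes))
        ## disjoint module gene sets drawn at random from the platform
        moduleGenes <- list()
        pool <- genes
        for (mn in names(config$modules)) {
            pick <- sample(pool, config$modules[[mn]])
            moduleGenes[[mn]] <- sort(pick)
            pool <- setdiff(pool, pick)
        }
        nonModule <- pool
        baseline <- stats::rnorm(config$nGenes, config$baselineMean,
                                 config$baselineSd)
        names(baseline) <- genes

        datasets <- list()
        idx <- 0L
        datasetGenotype <- character(0)
        for (gt in names(config$genotypes)) {
            spec <- config$genotypes[[gt]]
            for (d in seq_len(spec$nDatasets)) {
                idx <- idx + 1L
                dname <- sprintf("%s_ds%d", gt, d)
                datasets[[dname]] <- withSeed(
                    subSeed(config$seed, idx),
                    simulateDataset(dname, genes, baseline, moduleGenes,
                                    spec$effects, config))
                datasetGenotype[dname] <- gt
            }
        }

        sets <- lapply(moduleGenes, identity)
        names(sets) <- paste0("MOD_", toupper(names(moduleGenes)))
        if (config$nDecoySignatures > 0) {
            szs <- sample(config$signatureSizeRange[1]:
                          config$signatureSizeRange[2],
                          config$nDecoySignatures, replace = TRUE)
            for (i in seq_len(config$nDecoySignatures)) {
                nm <- sprintf("DECOY_%03d", i)
                sets[[nm]] <- sort(sample(nonModule,
                                          min(szs[i], length(nonModule))))
            }
        }
        signatures <- SignatureSet(sets, description = "simulated collection")

        effects <- lapply(config$genotypes, `[[`, "effects")
        list(datasets = datasets, signatures = signatures,
             truth = list(datasetGenotype = datasetGenotype,
                          modules = moduleGenes, effects = effects))
    })
}

## One dataset: baseline + planted test-arm effects + Gaussian noise.
simulateDataset <- function(name, genes, baseline, moduleGenes, effects,
                            config) {
    nC <- config$nControl; nT <- config$nTest
    samples <- c(sprintf("%s_ctl%d", name, seq_len(nC)),
                 sprintf("%s_tst%d", name, seq_len(nT)))
    m <- matrix(baseline, nrow = length(genes), ncol = nC + nT,
                dimnames = list(genes, samples))
    if (config$noiseSd > 0)
        m <- m + matrix(stats::rnorm(length(m), 0, config$noiseSd),
                        nrow = nrow(m))
    testCols <- (nC + 1):(nC + nT)
    for (mn in names(effects)) {
        m[moduleGenes[[mn]], testCols] <-
            m[moduleGenes[[mn]], testCols] + effects[[mn]]
    }
    ContrastExperiment(m, controlIds = samples[seq_len(nC)],
                       testIds = samples[testCols], name = name)
}

#' Degrade the control/test separation of a dataset
#'
#' Replaces exactly `kMisplaced` samples' expression vectors with fresh draws
#' from the opposite arm's generating distribution (per-gene Normal with the
#' opposite arm's sample mean and the pooled within-arm standard deviation),
#' so that the best principal-component bipartition misclassifies exactly
#' `min(kMisplaced, n - kMisplaced)` samples.  The condition is verified by
#' re-scoring with [pcaSeparationScore()]; if a draw does not achieve it, the
#' replacement is regenerated from a derived sub-seed, up to `maxRetries`.
#'
#' @param dataset a well-separated [ContrastExperiment-class].
#' @param kMisplaced number of samples to displace, `0 <= k <= n`.
#' @param seed RNG seed.
#' @param maxRetries bounded number of regeneration attempts.
#' @return The degraded [ContrastExperiment-class].
#' @export
degradeSeparation <- function(dataset, kMisplaced, seed = 1,
                              maxRetries = 25) {
    m <- log2ExprMatrix(dataset)
    n <- ncol(m)
    if (kMisplaced < 0 || kMisplaced > n)
        stop("kMisplaced must lie in [0, n samples]")
    if (kMisplaced == 0) return(dataset)
    ctl <- controlSamples(dataset); tst <- testSamples(dataset)
    muC <- rowMeans(m[, ctl, drop = FALSE])
    muT <- rowMeans(m[, tst, drop = FALSE])
    vC <- apply(m[, ctl, drop = FALSE], 1L, stats::var)
    vT <- apply(m[, tst, drop = FALSE], 1L, stats::var)
    nC <- length(ctl); nT <- length(tst)
    sdPooled <- sqrt(((nC - 1) * vC + (nT - 1) * vT) / (nC + nT - 2))
    target <- min(kMisplaced, n - kMisplaced)
    for (attempt in seq_len(maxRetries)) {
        cand <- withSeed(subSeed(seed, attempt), {
            pick <- sample(colnames(m), kMisplaced)
            m2 <- m
            for (s in pick) {
                mu <- if (s %in% ctl) muT else muC
                m2[, s] <- stats::rnorm(nrow(m), mu, sdPooled)
            }
            m2
        })
        out <- ContrastExperiment(cand, ctl, tst, datasetName(dataset))
        rep <- pcaSeparationScore(out)
        if (rep$nMisplaced == target) return(out)
    }
    stop("could not realize ", kMisplaced, " misplaced samples in ",
         maxRetries, " attempts; increase the planted effect size")
}

#' Generate a synthetic functional-term collection
#'
#' Builds GO/KEGG-style term sets around a simulation's planted modules: for
#' each module and each overlap level, a term of the module's size containing
#' the given fraction of module genes (remainder drawn from non-module
#' genes), plus random decoy terms disjoint from the modules.
#'
#' @param truth the `truth` element of [simulateCollection()] output.
#' @param nTerms total number of terms (module-overlap terms are created
#'   first; the remainder are decoys).
#' @param overlapLevels fractions of each module included in its graded
#'   terms.
#' @param universe character vector of all gene symbols to draw decoys from.
#' @param seed RNG seed.
#' @return A [SignatureSet-class] of terms.
#' @export
simulateTermCollection <- function(truth, nTerms = 30,
                                   overlapLevels = c(1, 0.5, 0.25),
                                   universe, seed = 1) {
    withSeed(seed, {
        moduleGenes <- truth$modules
        allModule <- unique(unlist(moduleGenes))
        background <- setdiff(universe, allModule)
        sets <- list()
        for (mn in names(moduleGenes)) {
            mg <- moduleGenes[[mn]]
            for (lv in overlapLevels) {
                o <- max(1L, round(lv * length(mg)))
                nm <- sprintf("TERM_%s_O%02d", toupper(mn), round(100 * lv))
                fill <- if (o < length(mg))
                    sample(background, length(mg) - o) else character(0)
                sets[[nm]] <- c(sample(mg, o), fill)
            }
        }
        nDecoy <- max(0L, nTerms - length(sets))
        for (i in seq_len(nDecoy)) {
            sz <- sample(10:50, 1)
            sets[[sprintf("TERMDECOY_%03d", i)]] <-
                sample(background, min(sz, length(background)))
        }
        SignatureSet(sets, description = "simulated term collection")
    })
}
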