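#' Pipeline configuration
#'
#' Bundles the file inputs, thresholds and seed for [runPipeline()].
#' Defaults are the conventional analysis settings: PCA score gate 0.75,
#' DEG thresholds FDR < 0.05 / FC > 2, signature overlap window 10-200,
#' nominal p < 0.05 recurrence selection, top-5% frequency selection, and
#' 3 x 3 two-way clusters.
#'
#' @param manifest path to a dataset manifest (see [readManifest()]).
#' @param signatureGmt path to the molecular-signature GMT.
#' @param termGmt optional path to a functional-term GMT; when `NULL` the
#'   term-enrichment stage is skipped.
#' @param outDir output directory.
#' @param pcaMin PCA-score acceptance threshold (inclusive).
#' @param fdrMax,fcMin DEG thresholds (strict).
#' @param sigMinOverlap,sigMaxOverlap inclusive signature size window.
#' @param pNominal nominal-p threshold for GSEA signature selection.
#' @param minDatasets minimum qualifying datasets for signature selection;
#'   `NULL` scales the conventional 10-of-18 rule to the accepted dataset
#'   count (at least 2).
#' @param fdrSelect FDR threshold for PAGE/GAGE signature selection;
#'   `NULL` uses 5e-21 (PAGE) or 5e-8 (GAGE).
#' @param topFrac top-fraction for CGS/PNS/URG selection.
#' @param kDatasetClusters,kFeatureClusters two-way cluster counts.
#' @param method enrichment method: `"gsea"`, `"page"` or `"gage"`.
#' @param nPerm GSEA permutation count.
#' @param seed master seed; stage/dataset sub-seeds derive from it.
#' @param applyLog2 passed to [readExpression()].
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(manifest, signatureGmt, termGmt = NULL,
                           outDir = "cscmeta_out",
                           pcaMin = 0.75, fdrMax = 0.05, fcMin = 2,
                           sigMinOverlap = 10, sigMaxOverlap = 200,
                           pNominal = 0.05, minDatasets = NULL,
                           fdrSelect = NULL,
                           topFrac = 0.05,
                           kDatasetClusters = 3, kFeatureClusters = 3,
                           method = c("gsea", "page", "gage"),
                           nPerm = 1000, seed = 1, applyLog2 = FALSE) {
    method <- match.arg(method)
    stopifnot(pcaMin >= 0.5, pcaMin <= 1, fdrMax > 0, fcMin > 0,
              sigMinOverlap >= 1, sigMaxOverlap >= sigMinOverlap,
              pNominal > 0, topFrac > 0, topFrac < 1, nPerm >= 10)
    cfg <- as.list(environment())
    class(cfg) <- "PipelineConfig"
    cfg
}

stageStep <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

stageLog <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full meta-analysis pipeline
#'
#' Executes qc -> deg -> enrich -> select -> cluster -> derive ->
#' term-enrich on the datasets listed in the manifest, writing every
#' stage's tables under `config$outDir` together with a machine-readable
#' run manifest (`run_manifest.json`) recording package version, seed and
#' parameters.  Re-running with the same config and seed reproduces
#' identical tables.  A stage error aborts with the stage name; outputs of
#' completed stages are retained.
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the main in-memory results: `reports`,
#'   `accepted`, `contrasts`, `degSets`, `profiles`, `selected`,
#'   `profileMatrix`, `assignment`, `cgs`, `urgDrg`, `termEnrichment`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- list()

    datasets <- stageStep("load", {
        mf <- readManifest(config$manifest)
        loadDatasets(mf, applyLog2 = config$applyLog2)
    })
    collection <- stageStep("load", readGmt(config$signatureGmt))
    stageLog("load", length(datasets), " datasets, ",
             length(collection), " signatures")

    ## ---- qc ----
    out$reports <- stageStep("qc", lapply(datasets, pcaSeparationScore))
    gate <- gateDatasets(out$reports, minScore = config$pcaMin)
    out$accepted <- gate$accepted
    stageStep("qc", writeTable(data.frame(
        name = names(out$reports),
        pca_score = vapply(out$reports, `[[`, numeric(1), "pcaScore"),
        n_misplaced = vapply(out$reports, `[[`, integer(1), "nMisplaced"),
        accepted = names(out$reports) %in% gate$accepted),
        file.path(config$outDir, "qc_scores.tsv")))
    for (nm in gate$rejected)
        stageLog("qc", "dataset ", nm, " rejected (score ",
                 signif(out$reports[[nm]]$pcaScore, 3), ")")
    if (length(gate$accepted) < 2)
        stageStep("qc", stop("fewer than 2 datasets pass the PCA gate"))
    datasets <- datasets[gate$accepted]
    stageLog("qc", length(datasets), " datasets accepted")

    ## ---- deg ----
    out$contrasts <- stageStep("deg", lapply(datasets, computeContrast,
                                             fdrMax = config$fdrMax,
                                             fcMin = config$fcMin))
    out$degSets <- lapply(out$contrasts, selectDegs,
                          fdrMax = config$fdrMax, fcMin = config$fcMin)
    stageStep("deg", {
        for (nm in names(out$contrasts))
            writeTable(out$contrasts[[nm]],
                       file.path(config$outDir, paste0("deg_", nm, ".tsv")))
        nonEmpty <- out$degSets[lengths(out$degSets) > 0]
        if (length(nonEmpty) >= 2) {
            M <- degOverlapMatrix(nonEmpty)
            writeTable(data.frame(dataset = rownames(M), M,
                                  check.names = FALSE),
                       file.path(config$outDir, "deg_overlap_matrix.tsv"))
        }
    })
    stageLog("deg", "DEG set sizes: ",
             paste(lengths(out$degSets), collapse = ", "))

    ## ---- enrich ----
    universes <- lapply(datasets, rownames)
    filtered <- stageStep("enrich", filterSignaturesByOverlap(
        collection, universes,
        minN = config$sigMinOverlap, maxN = config$sigMaxOverlap))
    stageLog("enrich", length(filtered), " signatures pass the size filter")
    out$profiles <- stageStep("enrich", {
        prof <- lapply(seq_along(datasets), function(i)
            profileDataset(datasets[[i]], filtered, method = config$method,
                           nPerm = config$nPerm,
                           seed = subSeed(config$seed, 1000 + i)))
        names(prof) <- names(datasets)
        for (nm in names(prof)) {
            tab <- enrichmentTable(prof[[nm]])
            le <- leadingEdges(prof[[nm]])
            tab$leading_edge <- vapply(tab$signature, function(s)
                paste(le[[s]], collapse = ";"), character(1))
            writeTable(tab, file.path(config$outDir,
                                      paste0("enrich_", nm, ".tsv")))
        }
        prof
    })

    ## ---- select ----
    out$selected <- stageStep("select", {
        if (config$method == "gsea") {
            minD <- config$minDatasets
            if (is.null(minD))
                minD <- max(2, ceiling(length(datasets) * 10 / 18))
            selectSignaturesGsea(out$profiles, pMax = config$pNominal,
                                 minDatasets = minD)
        } else {
            thr <- config$fdrSelect
            if (is.null(thr))
                thr <- if (config$method == "page") 5e-21 else 5e-8
            selectSignaturesByFdr(out$profiles, fdrMax = thr)
        }
    })
    stageLog("select", length(out$selected), " signatures selected")
    if (length(out$selected) < 2)
        stageStep("select",
                  stop("fewer than 2 signatures selected for clustering"))
    out$profileMatrix <- stageStep("select", {
        M <- buildProfile(out$selected, out$profiles, mode = "nes")
        writeTable(data.frame(dataset = rownames(M), M,
                              check.names = FALSE),
                   file.path(config$outDir, "profile_matrix.tsv"))
        M
    })

    ## ---- cluster ----
    out$assignment <- stageStep("cluster", {
        kR <- min(config$kDatasetClusters, nrow(out$profileMatrix))
        kC <- min(config$kFeatureClusters, ncol(out$profileMatrix))
        ga <- twoWayCluster(out$profileMatrix, kRows = kR, kCols = kC)
        writeTable(data.frame(dataset = names(datasetClusters(ga)),
                              cluster = datasetClusters(ga)),
                   file.path(config$outDir, "dataset_clusters.tsv"))
        writeTable(data.frame(feature = names(featureClusters(ga)),
                              cluster = featureClusters(ga)),
                   file.path(config$outDir, "feature_clusters.tsv"))
        M <- out$profileMatrix[ga@datasetOrder, ga@featureOrder,
                               drop = FALSE]
        writeTable(data.frame(dataset = rownames(M), M,
                              check.names = FALSE),
                   file.path(config$outDir, "heatmap_matrix.tsv"))
        rowHc <- hierarchicalCluster(
            pearsonMatrix(out$profileMatrix, "rows"),
            k = kR)$hclust
        colHc <- hierarchicalCluster(
            pearsonMatrix(out$profileMatrix, "cols"),
            k = kC)$hclust
        writeLines(c(dendrogramNewick(rowHc), dendrogramNewick(colHc)),
                   file.path(config$outDir, "dendrograms.nwk"))
        ga
    })
    stageLog("cluster", "dataset clusters: ",
             paste(datasetClusters(out$assignment), collapse = " "))

    ## ---- derive ----
    derived <- stageStep("derive", {
        cgs <- list()
        fc <- featureClusters(out$assignment)
        if (config$method == "gsea") {
            for (cl in sort(unique(fc))) {
                lbl <- paste0("CGS-", cl)
                cgs[[lbl]] <- extractCgs(names(fc)[fc == cl], out$profiles,
                                         topFrac = config$topFrac,
                                         label = lbl)
            }
        }
        urgDrg <- list()
        dc <- datasetClusters(out$assignment)
        if (config$method == "gsea") {
            for (cl in sort(unique(dc))) {
                lbl <- paste0("T", cl)
                prof <- out$profiles[names(dc)[dc == cl]]
                cons <- signatureConsistencySets(prof,
                                                topFrac = config$topFrac)
                urgDrg[[lbl]] <- c(selectUrgDrg(cons, prof,
                                                topFrac = config$topFrac,
                                                label = lbl),
                                   list(consistency = cons))
            }
        }
        for (d in c(cgs, unlist(lapply(urgDrg, function(x)
            list(x$urg, x$drg)), recursive = FALSE))) {
            if (!is(d, "DerivedGeneSet") || !length(d)) next
            writeTable(data.frame(gene = names(d),
                                  frequency = geneFrequency(d),
                                  n_contributing_signatures =
                                      length(d@signatures)),
                       file.path(config$outDir,
                                 paste0("derived_", d@label, ".tsv")))
        }
        list(cgs = cgs, urgDrg = urgDrg)
    })
    out$cgs <- derived$cgs
    out$urgDrg <- derived$urgDrg

    ## ---- term-enrich ----
    if (!is.null(config$termGmt)) {
        out$termEnrichment <- stageStep("term-enrich", {
            terms <- readGmt(config$termGmt)
            universe <- Reduce(intersect, universes)
            sets <- c(lapply(out$cgs, names),
                      unlist(lapply(out$urgDrg, function(x)
                          list(urg = names(x$urg), drg = names(x$drg))),
                          recursive = FALSE))
            sets <- sets[lengths(sets) > 0]
            res <- lapply(sets, function(g)
                suppressWarnings(fisherEnrichment(g, terms, universe)))
            for (nm in names(res))
                writeTable(res[[nm]],
                           file.path(config$outDir,
                                     paste0("terms_", nm, ".tsv")))
            if (length(res)) {
                M <- compareEnrichmentProfiles(res)
                writeTable(data.frame(set = rownames(M), M,
                                      check.names = FALSE),
                           file.path(config$outDir, "terms_neglogp.tsv"))
            }
            res
        })
    }

    ## ---- run manifest ----
    runInfo <- list(
        package = "cscmeta",
        version = as.character(utils::packageVersion("cscmeta")),
        seed = config$seed,
        method = config$method,
        parameters = config[!vapply(config, is.null, logical(1)) &
                            !names(config) %in%
                            c("manifest", "signatureGmt", "termGmt",
                              "outDir")],
        n_datasets_accepted = length(datasets),
        n_signatures_filtered = length(filtered),
        n_signatures_selected = length(out$selected))
    writeLines(jsonlite::toJSON(runInfo, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
               file.path(config$outDir, "run_manifest.json"))
    stageLog("done", "outputs written to ", config$outDir)
    invisible(out)
}
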