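#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' ContrastExperiment: one matched test-vs-control expression dataset
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes x samples matrix of log2 expression for a single matched contrast
#' (e.g. CSC vs NSC cells from one study).  The sample partition is stored as
#' a two-level `group` factor (`control`, `test`) in `colData`; the dataset
#' name lives in `metadata(x)$name`.
#'
#' Validity requires: unique gene symbols as rownames, no missing values in
#' the `log2expr` assay, and non-empty, disjoint control and test arms that
#' together cover all samples.
#'
#' @seealso [ContrastExperiment()] for the constructor,
#'   [controlSamples()], [testSamples()], [datasetName()].
#' @export
setClass("ContrastExperiment", contains = "SummarizedExperiment")

setValidity("ContrastExperiment", function(object) {
    msg <- character(0)
    if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2expr' is required")
    m <- SummarizedExperiment::assay(object, "log2expr")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        msg <- c(msg, "gene symbols (rownames) must be present and unique")
    if (anyNA(m))
        msg <- c(msg, "log2 expression matrix must not contain missing values")
    cd <- SummarizedExperiment::colData(object)
    if (!"group" %in% colnames(cd)) {
        msg <- c(msg, "colData must carry a 'group' column")
    } else {
        g <- cd$group
        if (!is.factor(g) || !identical(levels(g), c("control", "test")))
            msg <- c(msg, "'group' must be a factor with levels control, test")
        else if (any(table(g) == 0L))
            msg <- c(msg, "both control and test arms must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ContrastExperiment
#'
#' @param values numeric genes x samples matrix of log2 expression with gene
#'   symbols as rownames and sample identifiers as colnames.
#' @param controlIds,testIds character vectors of sample identifiers; must be
#'   disjoint, non-empty, and together cover every column of `values`.
#' @param name dataset identifier.
#' @return A [ContrastExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(24), 4, 6,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
#' ce <- ContrastExperiment(m, controlIds = paste0("s", 1:3),
#'                          testIds = paste0("s", 4:6), name = "demo")
#' controlSamples(ce)
#' @export
ContrastExperiment <- function(values, controlIds, testIds, name = "dataset") {
    if (!is.matrix(values) || !is.numeric(values))
        stop("'values' must be a numeric matrix")
    if (is.null(colnames(values)))
        stop("'values' must have sample identifiers as colnames")
    controlIds <- as.character(controlIds)
    testIds <- as.character(testIds)
    missing <- setdiff(c(controlIds, testIds), colnames(values))
    if (length(missing))
        stop("sample ids absent from expression matrix: ",
             paste(missing, collapse = ", "))
    if (length(intersect(controlIds, testIds)))
        stop("control and test ids must be disjoint")
    if (!length(controlIds) || !length(testIds))
        stop("control and test arms must both be non-empty")
    extra <- setdiff(colnames(values), c(controlIds, testIds))
    if (length(extra))
        stop("samples not assigned to either arm: ",
             paste(extra, collapse = ", "))
    grp <- factor(ifelse(colnames(values) %in% controlIds, "control", "test"),
                  levels = c("control", "test"))
    se <- SummarizedExperiment(
        assays = list(log2expr = values),
        colData = DataFrame(group = grp, row.names = colnames(values)))
    metadata(se)$name <- as.character(name)
    new("ContrastExperiment", se)
}

#' SignatureSet: a collection of named gene sets
#'
#' GMT-backed container for molecular signatures or functional terms: a named
#' list mapping signature name to a character vector of gene symbols.  Names
#' are unique, every set is non-empty, and genes within a set are unique
#' (set semantics).
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot description free-text provenance of the collection.
#' @seealso [SignatureSet()], [readGmt()], [geneSets()].
#' @export
setClass("SignatureSet",
         representation(sets = "list", description = "character"))

setValidity("SignatureSet", function(object) {
    s <- object@sets
    if (length(s)) {
        if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
            return("signature names must be present and unique")
        if (!all(vapply(s, is.character, logical(1))))
            return("every gene set must be a character vector")
        if (any(lengths(s) == 0L))
            return("every gene set must be non-empty")
    }
    TRUE
})

#' Construct a SignatureSet
#'
#' Duplicate genes within a set are collapsed; empty gene symbols dropped.
#'
#' @param sets named list of character vectors (signature name -> genes).
#' @param description free-text description of the collection source.
#' @return A [SignatureSet-class].
#' @examples
#' sig <- SignatureSet(list(SIG_A = c("TP53", "MYC"), SIG_B = c("A", "A", "B")))
#' lengths(geneSets(sig))
#' @export
SignatureSet <- function(sets = list(), description = NA_character_) {
    sets <- lapply(sets, function(g) unique(as.character(g[nzchar(g)])))
    new("SignatureSet", sets = sets, description = as.character(description))
}

#' EnrichmentProfile: per-signature enrichment results for one dataset
#'
#' One record per retained signature holding the enrichment statistic of the
#' chosen method (GSEA es/nes/permutation p, PAGE z, or GAGE-style Stouffer z),
#' the BH-adjusted fdr across signatures, and (for GSEA) the leading-edge gene
#' set.  Signatures skipped for structural reasons (no overlap, full overlap,
#' undefined NES) stay in the table with a non-`ok` flag and NA statistics.
#'
#' @slot dataset dataset name the profile belongs to.
#' @slot method one of `"gsea"`, `"page"`, `"gage"`.
#' @slot results data.frame with columns `signature`, `m` (overlap size),
#'   `es`, `nes`, `pNominal`, `fdr`, `flag`.
#' @slot leadingEdges named list (signature -> character vector), GSEA only.
#' @seealso [profileDataset()], [enrichmentTable()], [leadingEdges()].
#' @export
setClass("EnrichmentProfile",
         representation(dataset = "character", method = "character",
                        results = "data.frame", leadingEdges = "list"))

setValidity("EnrichmentProfile", function(object) {
    need <- c("signature", "m", "es", "nes", "pNominal", "fdr", "flag")
    if (!all(need %in% colnames(object@results)))
        return(paste("results must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(object@results$signature))
        return("duplicate signature rows")
    TRUE
})

#' GenotypeAssignment: two-way clustering of a profile matrix
#'
#' Result of two-way hierarchical clustering (Pearson distance, average
#' linkage) of a datasets x features profile matrix: cluster labels for the
#' datasets (the "genotypes") and for the features, dendrogram leaf orders,
#' and the dataset-dataset Pearson correlation matrix.
#'
#' @slot datasetClusters named integer vector, dataset -> cluster label.
#' @slot featureClusters named integer vector, feature -> cluster label.
#' @slot datasetOrder,featureOrder integer dendrogram leaf orders.
#' @slot datasetCor symmetric dataset correlation matrix with unit diagonal.
#' @slot profile the clustered profile matrix (datasets x features).
#' @seealso [twoWayCluster()], [datasetClusters()], [featureClusters()].
#' @export
setClass("GenotypeAssignment",
         representation(datasetClusters = "integer",
                        featureClusters = "integer",
                        datasetOrder = "integer",
                        featureOrder = "integer",
                        datasetCor = "matrix",
                        profile = "matrix"))

setValidity("GenotypeAssignment", function(object) {
    if (is.null(names(object@datasetClusters)))
        return("datasetClusters must be named")
    if (is.null(names(object@featureClusters)))
        return("featureClusters must be named")
    dc <- object@datasetCor
    if (nrow(dc) && (!isTRUE(all.equal(dc, t(dc), tolerance = 1e-8)) ||
                     !isTRUE(all.equal(unname(diag(dc)), rep(1, nrow(dc))))))
        return("datasetCor must be symmetric with unit diagonal")
    TRUE
})

#' DerivedGeneSet: a frequency-selected gene set (CGS, URG or DRG)
#'
#' Genes selected by their frequency of occurrence as leading-edge genes
#' across a group of signatures, with the per-gene counts and the
#' contributing signature names kept as evidence.
#'
#' @slot label set label, e.g. `"CGS-1"`, `"URG-T1"`.
#' @slot genes selected gene symbols.
#' @slot frequency named integer: for every selected gene, the number of
#'   contributing signatures in whose leading edge it occurred.
#' @slot signatures names of the contributing signatures.
#' @seealso [extractCgs()], [selectUrgDrg()], [geneFrequency()].
#' @export
setClass("DerivedGeneSet",
         representation(label = "character", genes = "character",
                        frequency = "integer", signatures = "character"))

setValidity("DerivedGeneSet", function(object) {
    if (!setequal(object@genes, names(object@frequency)))
        return("frequency must be named by exactly the selected genes")
    if (length(object@frequency) && any(object@frequency < 1L))
        return("every selected gene must have frequency >= 1")
    TRUE
})
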