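## Generics and accessor methods for the package's S4 classes.

#' @rdname ContrastExperiment-class
#' @param x a package object.
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))

#' @rdname ContrastExperiment-class
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname ContrastExperiment-class
#' @export
setGeneric("testSamples", function(x) standardGeneric("testSamples"))

#' @rdname SignatureSet-class
#' @param x a package object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname EnrichmentProfile-class
#' @param x a package object.
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname EnrichmentProfile-class
#' @export
setGeneric("leadingEdges", function(x) standardGeneric("leadingEdges"))

#' @rdname GenotypeAssignment-class
#' @param x a package object.
#' @export
setGeneric("datasetClusters", function(x) standardGeneric("datasetClusters"))

#' @rdname GenotypeAssignment-class
#' @export
setGeneric("featureClusters", function(x) standardGeneric("featureClusters"))

#' @rdname DerivedGeneSet-class
#' @param x a package object.
#' @export
setGeneric("geneFrequency", function(x) standardGeneric("geneFrequency"))

#' @rdname ContrastExperiment-class
#' @export
setMethod("datasetName", "ContrastExperiment", function(x)
    as.character(S4Vectors::metadata(x)$name))

#' @rdname ContrastExperiment-class
#' @export
setMethod("controlSamples", "ContrastExperiment", function(x)
    rownames(SummarizedExperiment::colData(x))[
        SummarizedExperiment::colData(x)$group == "control"])

#' @rdname ContrastExperiment-class
#' @export
setMethod("testSamples", "ContrastExperiment", function(x)
    rownames(SummarizedExperiment::colData(x))[
        SummarizedExperiment::colData(x)$group == "test"])

setMethod("show", "ContrastExperiment", function(object) {
    cat("ContrastExperiment:", datasetName(object), "\n")
    cat(" ", nrow(object), "genes;",
        length(controlSamples(object)), "control vs",
        length(testSamples(object)), "test samples\n")
})

#' @rdname SignatureSet-class
#' @export
setMethod("geneSets", "SignatureSet", function(x) x@sets)

#' @rdname SignatureSet-class
#' @export
setMethod("names", "SignatureSet", function(x) names(x@sets))

#' @rdname SignatureSet-class
#' @export
setMethod("length", "SignatureSet", function(x) length(x@sets))

#' @rdname SignatureSet-class
#' @param i index or signature name(s).
#' @export
setMethod("[[", "SignatureSet", function(x, i) x@sets[[i]])

#' @rdname SignatureSet-class
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SignatureSet", function(x, i, j, ..., drop = FALSE)
    new("SignatureSet", sets = x@sets[i], description = x@description))

setMethod("show", "SignatureSet", function(object) {
    cat("SignatureSet of", length(object), "gene sets")
    if (!is.na(object@description)) cat(" (", object@description, ")", sep = "")
    cat("\n")
    if (length(object)) {
        sz <- lengths(object@sets)
        cat("  set sizes:", min(sz), "-", max(sz),
            "(median", stats::median(sz), ")\n")
    }
})

#' @rdname EnrichmentProfile-class
#' @export
setMethod("datasetName", "EnrichmentProfile", function(x) x@dataset)

#' @rdname EnrichmentProfile-class
#' @export
setMethod("enrichmentTable", "EnrichmentProfile", function(x) x@results)

#' @rdname EnrichmentProfile-class
#' @export
setMethod("leadingEdges", "EnrichmentProfile", function(x) x@leadingEdges)

setMethod("show", "EnrichmentProfile", function(object) {
    ok <- sum(object@results$flag == "ok")
    cat("EnrichmentProfile (", object@method, ") for dataset ",
        object@dataset, "\n  ", nrow(object@results), " signatures (",
        ok, " scored)\n", sep = "")
})

#' @rdname GenotypeAssignment-class
#' @export
setMethod("datasetClusters", "GenotypeAssignment", function(x)
    x@datasetClusters)

#' @rdname GenotypeAssignment-class
#' @export
setMethod("featureClusters", "GenotypeAssignment", function(x)
    x@featureClusters)

setMethod("show", "GenotypeAssignment", function(object) {
    cat("GenotypeAssignment:",
        length(object@datasetClusters), "datasets in",
        length(unique(object@datasetClusters)), "clusters;",
        length(object@featureClusters), "features in",
        length(unique(object@featureClusters)), "clusters\n")
})

#' @rdname DerivedGeneSet-class
#' @export
setMethod("geneFrequency", "DerivedGeneSet", function(x) x@frequency)

#' @rdname DerivedGeneSet-class
#' @export
setMethod("names", "DerivedGeneSet", function(x) x@genes)

#' @rdname DerivedGeneSet-class
#' @export
setMethod("length", "DerivedGeneSet", function(x) length(x@genes))

setMethod("show", "DerivedGeneSet", function(object) {
    cat("DerivedGeneSet", object@label, ":", length(object@genes),
        "genes from", length(object@signatures), "signatures\n")
})
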