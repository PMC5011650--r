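#' Read a GMT signature file
#'
#' Parses the tab-delimited GMT format used to distribute molecular signature
#' collections (one signature per line: name, description, then gene symbols).
#' Duplicate genes within a line are collapsed and empty gene fields dropped.
#'
#' @param path path to a GMT file.
#' @return A [SignatureSet-class].
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("SIG_A\tdesc\tTP53\tMYC", f)
#' readGmt(f)
#' @export
readGmt <- function(path) {
    if (!file.exists(path)) stop("GMT file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    sets <- vector("list", length(lines))
    nms <- character(length(lines))
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3)
            stop("malformed GMT line ", i, ": fewer than 3 tab-separated fields")
        nms[i] <- f[1]
        genes <- unique(f[-(1:2)])
        sets[[i]] <- genes[nzchar(genes)]
    }
    dup <- nms[duplicated(nms)]
    if (length(dup))
        stop("duplicate signature name(s): ", paste(unique(dup), collapse = ", "))
    names(sets) <- nms
    SignatureSet(sets, description = basename(path))
}

#' Write a SignatureSet to GMT
#'
#' @param collection a [SignatureSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(collection, path) {
    stopifnot(is(collection, "SignatureSet"))
    lines <- vapply(names(collection), function(nm) {
        paste(c(nm, "na", collection[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read an expression matrix TSV as a ContrastExperiment
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose remaining columns are samples (header row of sample identifiers).
#' Rows with duplicate gene symbols are collapsed by the mean of their log2
#' values; rows containing any missing value are dropped.
#'
#' @param path path to the expression TSV.
#' @param controlIds,testIds sample identifiers of the two arms; every id
#'   must appear in the file header.
#' @param name dataset name (defaults to the file base name).
#' @param applyLog2 if `TRUE`, values are transformed by `log2(x + 1)` after
#'   loading (for matrices stored on the linear scale).
#' @return A [ContrastExperiment-class].
#' @export
readExpression <- function(path, controlIds, testIds,
                           name = sub("\\.[^.]*$", "", basename(path)),
                           applyLog2 = FALSE) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("expression TSV must have gene and sample columns")
    ids <- c(controlIds, testIds)
    missing <- setdiff(ids, colnames(df)[-1])
    if (length(missing))
        stop("sample id(s) absent from header: ",
             paste(missing, collapse = ", "))
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    ## collapse duplicate gene rows by mean
    if (anyDuplicated(genes)) {
        m <- rowsum(m, group = genes, reorder = FALSE) /
            as.vector(table(factor(genes, levels = unique(genes))))
        genes <- rownames(m)
    }
    rownames(m) <- genes
    keep <- !apply(m, 1L, anyNA)
    m <- m[keep, , drop = FALSE]
    if (applyLog2) m <- log2(m + 1)
    ContrastExperiment(m[, ids, drop = FALSE], controlIds, testIds, name)
}

#' Write a ContrastExperiment to an expression TSV
#'
#' @param dataset a [ContrastExperiment-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(dataset, path) {
    m <- log2ExprMatrix(dataset)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    writeTable(df, path)
}

#' Read a dataset manifest
#'
#' The manifest is a TSV with columns `name`, `file`, `control`, `test`;
#' `control` and `test` hold semicolon-joined sample identifiers.  File paths
#' are resolved relative to the manifest's directory when not absolute.
#'
#' @param path manifest path.
#' @return data.frame with one row per dataset (columns `name`, `file`,
#'   `control`, `test`, the latter two as list columns of ids).
#' @export
readManifest <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "file", "control", "test")
    if (!all(need %in% colnames(df)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df$name))
        stop("duplicate dataset name(s) in manifest")
    base <- dirname(path)
    df$file <- ifelse(grepl("^(/|[A-Za-z]:)", df$file), df$file,
                      file.path(base, df$file))
    df$control <- strsplit(df$control, ";", fixed = TRUE)
    df$test <- strsplit(df$test, ";", fixed = TRUE)
    df
}

#' Load every dataset referenced by a manifest
#'
#' @param manifest a data.frame from [readManifest()].
#' @param applyLog2 passed to [readExpression()].
#' @return named list of [ContrastExperiment-class] objects.
#' @export
loadDatasets <- function(manifest, applyLog2 = FALSE) {
    out <- lapply(seq_len(nrow(manifest)), function(i) {
        readExpression(manifest$file[[i]],
                       controlIds = manifest$control[[i]],
                       testIds = manifest$test[[i]],
                       name = manifest$name[[i]],
                       applyLog2 = applyLog2)
    })
    names(out) <- manifest$name
    out
}

#' Write datasets plus a manifest to a directory
#'
#' Emits one expression TSV per dataset and a `manifest.tsv` indexing them,
#' in the format [readManifest()] reads back.
#'
#' @param datasets named list of [ContrastExperiment-class] objects.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(datasets, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rows <- lapply(datasets, function(d) {
        f <- paste0(datasetName(d), ".tsv")
        writeExpression(d, file.path(dir, f))
        data.frame(name = datasetName(d), file = f,
                   control = paste(controlSamples(d), collapse = ";"),
                   test = paste(testSamples(d), collapse = ";"),
                   stringsAsFactors = FALSE)
    })
    mpath <- file.path(dir, "manifest.tsv")
    writeTable(do.call(rbind, rows), mpath)
    invisible(mpath)
}

#' Write a result table as TSV
#'
#' Tab-separated, header row, no quoting or row names; numeric columns keep
#' at least 15 significant digits so tables round-trip through [readTable()]
#' without loss.
#'
#' @param records a data.frame (possibly zero rows).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(records, path) {
    stopifnot(is.data.frame(records))
    df <- records
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

#' Read a TSV written by [writeTable()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTable <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
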