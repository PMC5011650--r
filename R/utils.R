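## Internal helpers: seed plumbing and ordering conventions.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        has_old <- exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE)
        old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
        set.seed(as.integer(seed))
        on.exit({
            if (has_old) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
    }
    force(code)
}

# Deterministic sub-seed from a master seed and an index; stays < 2^31.
subSeed <- function(seed, index) {
    as.integer((as.numeric(seed) + 10007 * as.numeric(index)) %% 2147483647)
}

# Order values descending with deterministic lexicographic (C-locale)
# tie-break on the accompanying names.
orderDescWithNames <- function(values, nms) {
    order(-values, nms, method = "radix")
}

log2ExprMatrix <- function(dataset) {
    stopifnot(is(dataset, "ContrastExperiment"))
    SummarizedExperiment::assay(dataset, "log2expr")
}
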