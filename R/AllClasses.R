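#' @importFrom methods new is validObject setClass setGeneric setMethod
#'   setValidity callNextMethod slot
#' @import S4Vectors
#' @import SummarizedExperiment
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
NULL

#' Compound-by-cell-line screen container
#'
#' A `ScreenExperiment` holds pooled-screen viability responses (compounds in
#' rows, cell lines in columns) together with a per-line lineage annotation in
#' `colData` and the response kind (`"log2fc"` for replicate-collapsed log2
#' fold change vs vehicle, `"auc"` for dose-response area under the curve) in
#' `metadata`.  Missing (compound, line) measurements are `NA`, never 0.
#'
#' @slot .  Extends \linkS4class{SummarizedExperiment}; the single assay is
#'   named `"response"`.
#' @export
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
    msg <- character()
    if (!"response" %in% assayNames(object))
        msg <- c(msg, "assay 'response' is required")
    if (!"lineage" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'lineage' column")
    kind <- metadata(object)$screenKind
    if (is.null(kind) || !kind %in% c("log2fc", "auc"))
        msg <- c(msg, "metadata$screenKind must be 'log2fc' or 'auc'")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated cell line identifiers")
    if (length(msg)) msg else TRUE
})

#' Gene-by-cell-line dependency score container
#'
#' Holds per-gene, per-line dependency scores (DEMETER2 convention: more
#' negative means the line is more dependent on the gene) with a lineage
#' annotation in `colData`.  Lines without a lineage label carry `NA` and are
#' excluded from lineage summaries.
#'
#' @export
setClass("DependencyExperiment", contains = "SummarizedExperiment")

setValidity("DependencyExperiment", function(object) {
    msg <- character()
    if (!"score" %in% assayNames(object))
        msg <- c(msg, "assay 'score' is required")
    if (!"lineage" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'lineage' column")
    sc <- assay(object, "score")
    if (any(is.infinite(sc)))
        msg <- c(msg, "scores must be finite")
    if (length(msg)) msg else TRUE
})

#' Unified splice-junction read matrix
#'
#' Rows are splice junctions (first to last intronic base, 1-based inclusive,
#' as reported by STAR) held as `rowRanges`; columns are samples or, after
#' averaging, genotypes.  The processing state is tracked in
#' `metadata(x)$state` and advances `raw` -> `normalized` -> `averaged` ->
#' `filtered`; each pipeline step checks the state of its input so steps
#' cannot be applied out of order.  Junctions absent from a sample are 0, not
#' `NA`: SJ.out.tab reports only observed junctions, so absence means no
#' supporting read.
#'
#' @export
setClass("JunctionExperiment", contains = "RangedSummarizedExperiment")

setValidity("JunctionExperiment", function(object) {
    msg <- character()
    if (!"reads" %in% assayNames(object))
        msg <- c(msg, "assay 'reads' is required")
    st <- metadata(object)$state
    if (is.null(st) ||
        !st %in% c("raw", "normalized", "averaged", "filtered"))
        msg <- c(msg, paste("metadata$state must be one of raw, normalized,",
                            "averaged, filtered"))
    if (anyNA(assay(object, "reads")))
        msg <- c(msg, "junction values must not be NA (absent junctions are 0)")
    if (length(msg)) msg else TRUE
})

#' rMATS-style differential-splicing event table
#'
#' One of the five rMATS event categories (SE, A5SS, A3SS, MXE, RI) with one
#' row per event.  `events` keeps the statistical columns (`pValue`, `fdr`,
#' `incLevelDiff`) plus the category-specific coordinate tuple; `eventKey`
#' is the coordinate-based identity used for cross-run overlap (rMATS numeric
#' IDs are not stable across runs).  `provenance` records the filters already
#' applied.
#'
#' @slot events DataFrame of events.
#' @slot category one of `"SE"`, `"A5SS"`, `"A3SS"`, `"MXE"`, `"RI"`.
#' @slot provenance list describing applied filters and drop counts.
#' @export
setClass("SpliceEventTable",
    representation(events = "DFrame", category = "character",
                   provenance = "list"),
    prototype(provenance = list()))

setValidity("SpliceEventTable", function(object) {
    msg <- character()
    if (length(object@category) != 1L ||
        !object@category %in% rmatsCategories())
        msg <- c(msg, "category must be one of SE, A5SS, A3SS, MXE, RI")
    need <- c("geneId", "geneSymbol", "chrom", "strand", "pValue", "fdr",
              "incLevelDiff", "eventKey")
    miss <- setdiff(need, colnames(object@events))
    if (length(miss))
        msg <- c(msg, paste("events is missing columns:",
                            paste(miss, collapse = ", ")))
    dpsi <- object@events$incLevelDiff
    if (length(dpsi) && any(abs(dpsi) > 1, na.rm = TRUE))
        msg <- c(msg, "incLevelDiff must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Permutation test configuration
#'
#' Settings for the lineage-selectivity permutation null.  When the number of
#' distinct target-group assignments `choose(n, k)` is at most
#' `exhaustiveLimit` the null is enumerated exactly; otherwise `nDraws`
#' Monte-Carlo k-subsets are drawn and the empirical p-value uses the add-one
#' estimator, which never returns 0.
#'
#' @slot nDraws number of Monte-Carlo draws (default 1e5).
#' @slot seed integer seed for the per-compound random substreams.
#' @slot alternative `"less"` (default: selective toxicity, negative mean
#'   difference), `"greater"`, or `"two_sided"`.
#' @slot exhaustiveLimit switch to exact enumeration when
#'   `choose(n, k) <= exhaustiveLimit`.
#' @slot minTargetN,minOtherN minimum group sizes for a compound to be ranked.
#' @export
setClass("PermutationConfig",
    representation(nDraws = "integer", seed = "integer",
                   alternative = "character", exhaustiveLimit = "numeric",
                   minTargetN = "integer", minOtherN = "integer"))

setValidity("PermutationConfig", function(object) {
    msg <- character()
    if (object@nDraws < 1L) msg <- c(msg, "nDraws must be >= 1")
    if (!object@alternative %in% c("less", "greater", "two_sided"))
        msg <- c(msg, "alternative must be less, greater or two_sided")
    if (object@exhaustiveLimit < 1) msg <- c(msg, "exhaustiveLimit must be >= 1")
    if (object@minTargetN < 1L || object@minOtherN < 1L)
        msg <- c(msg, "minimum group sizes must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname PermutationConfig-class
#' @param nDraws,seed,alternative,exhaustiveLimit,minTargetN,minOtherN see slots.
#' @return A `PermutationConfig` object.
#' @examples
#' PermutationConfig(nDraws = 1000, seed = 1)
#' @export
PermutationConfig <- function(nDraws = 100000L, seed = 1L,
                              alternative = c("less", "greater", "two_sided"),
                              exhaustiveLimit = 100000,
                              minTargetN = 2L, minOtherN = 2L) {
    new("PermutationConfig", nDraws = as.integer(nDraws),
        seed = as.integer(seed), alternative = match.arg(alternative),
        exhaustiveLimit = as.numeric(exhaustiveLimit),
        minTargetN = as.integer(minTargetN), minOtherN = as.integer(minOtherN))
}

setMethod("show", "PermutationConfig", function(object) {
    cat("PermutationConfig: nDraws =", object@nDraws,
        "| alternative =", object@alternative,
        "| exhaustiveLimit =", object@exhaustiveLimit,
        "| min group sizes =", object@minTargetN, "/", object@minOtherN,
        "| seed =", object@seed, "\n")
})

setMethod("show", "SpliceEventTable", function(object) {
    cat("SpliceEventTable:", nrow(object@events), object@category,
        "events\n")
    if (length(object@provenance))
        cat("  filters:", paste(names(object@provenance), collapse = ", "),
            "\n")
})

setMethod("show", "ScreenExperiment", function(object) {
    callNextMethod()
    cat("screenKind:", metadata(object)$screenKind, "|",
        length(unique(stats::na.omit(colData(object)$lineage))),
        "lineages\n")
})

setMethod("show", "JunctionExperiment", function(object) {
    callNextMethod()
    cat("state:", metadata(object)$state, "\n")
})
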