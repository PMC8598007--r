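#' @rdname ScreenExperiment-class
#' @param x a `ScreenExperiment` or `DependencyExperiment`.
#' @export
setGeneric("lineages", function(x) standardGeneric("lineages"))

#' @rdname ScreenExperiment-class
#' @export
setMethod("lineages", "SummarizedExperiment", function(x) {
    stats::setNames(as.character(colData(x)$lineage), colnames(x))
})

#' @rdname ScreenExperiment-class
#' @export
setGeneric("screenKind", function(x) standardGeneric("screenKind"))

#' @rdname ScreenExperiment-class
#' @export
setMethod("screenKind", "ScreenExperiment",
          function(x) metadata(x)$screenKind)

#' @rdname JunctionExperiment-class
#' @param x a `JunctionExperiment`.
#' @export
setGeneric("junctionState", function(x) standardGeneric("junctionState"))

#' @rdname JunctionExperiment-class
#' @export
setMethod("junctionState", "JunctionExperiment",
          function(x) metadata(x)$state)

#' @rdname SpliceEventTable-class
#' @param x a `SpliceEventTable`.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname SpliceEventTable-class
#' @export
setMethod("events", "SpliceEventTable", function(x) x@events)

#' @rdname SpliceEventTable-class
#' @export
setGeneric("category", function(x) standardGeneric("category"))

#' @rdname SpliceEventTable-class
#' @export
setMethod("category", "SpliceEventTable", function(x) x@category)

#' @rdname SpliceEventTable-class
#' @export
setMethod("nrow", "SpliceEventTable", function(x) nrow(x@events))
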