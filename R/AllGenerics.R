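#' @rdname ExpressionDataset-class
#' @param object an object.
#' @export
setGeneric("datasetId", function(object) standardGeneric("datasetId"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("probeIds", function(object) standardGeneric("probeIds"))

#' @rdname ExpressionDataset-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname GeneSetCollection-class
#' @param object an object.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneUniverse", function(object) standardGeneric("geneUniverse"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setDescriptions",
           function(object) standardGeneric("setDescriptions"))

#' Extract the underlying edge record table
#' @param object a [PPIEdgeTable].
#' @return data.frame of `(gene_a, gene_b, source_db)` records.
#' @export
setGeneric("ppiEdges", function(object) standardGeneric("ppiEdges"))

#' Extract a result table as a data.frame
#'
#' Accessor for the tabular payload of report/result objects
#' ([FilterReport], [CorrelationResult]).
#'
#' @param object a result object.
#' @return data.frame, one row per record.
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname InteractionNetwork-class
#' @param object an object.
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))
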