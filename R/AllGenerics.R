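#' @rdname StageExpression-class
#' @param x an object with an expression matrix
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname StageExpression-class
#' @export
setGeneric("stageNames", function(x) standardGeneric("stageNames"))

#' @rdname StandardizedExpression-class
#' @param x a StandardizedExpression
#' @export
setGeneric("auditCounts", function(x) standardGeneric("auditCounts"))

#' @rdname GeneEvolStats-class
#' @param x a GeneEvolStats
#' @export
setGeneric("evolStats", function(x) standardGeneric("evolStats"))

#' @rdname IndexProfile-class
#' @param x an IndexProfile
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname IndexProfile-class
#' @export
setGeneric("nGenesUsed", function(x) standardGeneric("nGenesUsed"))

#' @rdname IndexProfile-class
#' @export
setGeneric("weightName", function(x) standardGeneric("weightName"))

#' @rdname PhylostratumMap-class
#' @param x a PhylostratumMap
#' @export
setGeneric("psAssignments", function(x) standardGeneric("psAssignments"))

#' @rdname PhylostratumMap-class
#' @export
setGeneric("unassignedGenes", function(x) standardGeneric("unassignedGenes"))

#' @rdname GeneCatalog-class
#' @param x a GeneCatalog
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' @rdname LineageMap-class
#' @param x a LineageMap
#' @export
setGeneric("taxonToPs", function(x) standardGeneric("taxonToPs"))

#' @rdname LineageMap-class
#' @export
setGeneric("nStrata", function(x) standardGeneric("nStrata"))

setMethod("exprValues", "StageExpression", function(x) x@values)
setMethod("exprValues", "StandardizedExpression", function(x) x@values)
setMethod("stageNames", "StageExpression", function(x) x@stageOrder)
setMethod("stageNames", "StandardizedExpression", function(x) colnames(x@values))
setMethod("auditCounts", "StandardizedExpression", function(x) x@audit)
setMethod("evolStats", "GeneEvolStats", function(x) x@stats)
setMethod("profileValues", "IndexProfile", function(x) x@values)
setMethod("nGenesUsed", "IndexProfile", function(x) x@nGenesUsed)
setMethod("weightName", "IndexProfile", function(x) x@weightName)
setMethod("psAssignments", "PhylostratumMap", function(x) x@ps)
setMethod("unassignedGenes", "PhylostratumMap", function(x) x@unassigned)
setMethod("catalogTable", "GeneCatalog", function(x) x@genes)
setMethod("taxonToPs", "LineageMap", function(x) x@taxonToPs)
setMethod("nStrata", "LineageMap", function(x) x@nStrata)
setMethod("nStrata", "GeneCatalog", function(x) x@nStrata)
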