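#' @export
setGeneric("boundaryRing", function(x) standardGeneric("boundaryRing"))

#' @export
setGeneric("paddockArea", function(x) standardGeneric("paddockArea"))

#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @export
setGeneric("rasterValues", function(x) standardGeneric("rasterValues"))

#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @export
setGeneric("lriValues", function(x) standardGeneric("lriValues"))

#' @export
setGeneric("lriCounts", function(x) standardGeneric("lriCounts"))

#' @export
setGeneric("aggregateLRI", function(x) standardGeneric("aggregateLRI"))

#' @export
setGeneric("residencyLevel", function(x) standardGeneric("residencyLevel"))

#' @export
setGeneric("oobR2", function(x) standardGeneric("oobR2"))

#' @export
setGeneric("oobMSE", function(x) standardGeneric("oobMSE"))

#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))
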