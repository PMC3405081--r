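#' @import methods
NULL

#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))

#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @export
setGeneric("gridBounds", function(x) standardGeneric("gridBounds"))

#' @export
setGeneric("crsName", function(x) standardGeneric("crsName"))

#' @export
setGeneric("nodataValue", function(x) standardGeneric("nodataValue"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("geomType", function(x) standardGeneric("geomType"))

#' @export
setGeneric("featureCoords", function(x) standardGeneric("featureCoords"))

#' @export
setGeneric("featureAttrs", function(x) standardGeneric("featureAttrs"))

#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @export
setGeneric("jurisdiction", function(x) standardGeneric("jurisdiction"))

#' @export
setGeneric("rules", function(x) standardGeneric("rules"))
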