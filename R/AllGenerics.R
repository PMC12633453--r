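#' @include AllClasses.R
NULL

#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @export
setGeneric("designMatrix", function(object, ...) standardGeneric("designMatrix"))

#' @export
setGeneric("offsets", function(object, ...) standardGeneric("offsets"))

#' @export
setGeneric("locationLabels", function(object, ...) standardGeneric("locationLabels"))

#' @export
setGeneric("featureNames", function(object, ...) standardGeneric("featureNames"))

#' @export
setGeneric("nLocations", function(object, ...) standardGeneric("nLocations"))

#' @export
setGeneric("nNodes", function(object, ...) standardGeneric("nNodes"))

#' @export
setGeneric("degrees", function(object, ...) standardGeneric("degrees"))

#' @export
setGeneric("graphEdges", function(object, ...) standardGeneric("graphEdges"))

#' @export
setGeneric("nComponents", function(object, ...) standardGeneric("nComponents"))

#' @export
setGeneric("groupSizes", function(object, ...) standardGeneric("groupSizes"))

#' @export
setGeneric("nGroups", function(object, ...) standardGeneric("nGroups"))

#' @export
setGeneric("isSingleton", function(object, ...) standardGeneric("isSingleton"))

#' @export
setGeneric("groupOf", function(object, ...) standardGeneric("groupOf"))

#' @export
setGeneric("betaDraws", function(object, ...) standardGeneric("betaDraws"))

#' @export
setGeneric("deltaDraws", function(object, ...) standardGeneric("deltaDraws"))

#' @export
setGeneric("phiDraws", function(object, ...) standardGeneric("phiDraws"))

#' @export
setGeneric("traces", function(object, ...) standardGeneric("traces"))

#' @export
setGeneric("pip", function(object, ...) standardGeneric("pip"))

#' @export
setGeneric("credibleIntervals", function(object, level = 0.95, ...)
  standardGeneric("credibleIntervals"))

#' @export
setGeneric("etiExclusionLevel", function(object, ...)
  standardGeneric("etiExclusionLevel"))

#' @export
setGeneric("selectFeatures", function(object, ...) standardGeneric("selectFeatures"))

#' @export
setGeneric("gewekeTable", function(object, ...) standardGeneric("gewekeTable"))
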