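#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("connValues", function(object) standardGeneric("connValues"))

#' @rdname accessors
#' @export
setGeneric("connScale", function(object) standardGeneric("connScale"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("roiGroups", function(object) standardGeneric("roiGroups"))

#' @rdname accessors
#' @export
setGeneric("roiKind", function(object) standardGeneric("roiKind"))

#' @rdname accessors
#' @export
setGeneric("nRois", function(object) standardGeneric("nRois"))

#' @rdname accessors
#' @export
setGeneric("roiCoordinates", function(object) standardGeneric("roiCoordinates"))

#' @rdname accessors
#' @export
setGeneric("tsData", function(object) standardGeneric("tsData"))

#' @rdname accessors
#' @export
setGeneric("stackValues", function(object) standardGeneric("stackValues"))

#' @rdname accessors
#' @export
setGeneric("stackSubjects", function(object) standardGeneric("stackSubjects"))

#' @rdname accessors
#' @export
setGeneric("observedDiff", function(object) standardGeneric("observedDiff"))

#' @rdname accessors
#' @export
setGeneric("pRaw", function(object) standardGeneric("pRaw"))

#' @rdname accessors
#' @export
setGeneric("pAdj", function(object) standardGeneric("pAdj"))

#' @rdname accessors
#' @export
setGeneric("isSignificant", function(object) standardGeneric("isSignificant"))

#' @rdname accessors
#' @export
setGeneric("significantEdges",
           function(object) standardGeneric("significantEdges"))

#' @rdname accessors
#' @export
setGeneric("edgeCounts", function(object) standardGeneric("edgeCounts"))

#' @rdname accessors
#' @export
setGeneric("nodeCounts", function(object, kind = c("seed", "atlas"))
  standardGeneric("nodeCounts"))

#' @rdname accessors
#' @export
setGeneric("perPatientCounts",
           function(object) standardGeneric("perPatientCounts"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(object) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(object) standardGeneric("graphNodes"))
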