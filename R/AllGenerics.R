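#' @rdname DistanceMatrix-class
#' @param x an object
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))

#' @rdname DistanceMatrix-class
#' @export
setGeneric("distKind", function(x) standardGeneric("distKind"))

#' @rdname DistanceMatrix-class
#' @param object an object
#' @export
setGeneric("sampleNames", function(object) standardGeneric("sampleNames"))

#' @rdname Ordination-class
#' @param x an object
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname Ordination-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname Ordination-class
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))

#' @rdname EnvRasterStack-class
#' @param x an object
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname EnvRasterStack-class
#' @param name layer name
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname EnvRasterStack-class
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname ReadCountMatrix-class
#' @param x an object
#' @export
setGeneric("alleleCounts", function(x) standardGeneric("alleleCounts"))

#' @rdname ReadCountMatrix-class
#' @export
setGeneric("sampleCoverage", function(x) standardGeneric("sampleCoverage"))

#' @rdname ForestModel-class
#' @param x an object
#' @export
setGeneric("importanceTable", function(x) standardGeneric("importanceTable"))

#' @rdname ForestModel-class
#' @export
setGeneric("retainedPredictors", function(x) standardGeneric("retainedPredictors"))

#' @rdname ForestModel-class
#' @export
setGeneric("totalExplained", function(x) standardGeneric("totalExplained"))

#' @rdname ForestModel-class
#' @export
setGeneric("trainingRanges", function(x) standardGeneric("trainingRanges"))
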