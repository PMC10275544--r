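#' @rdname SignalSet-class
#' @param object,x a package object
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname SignalSet-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname SignalSet-class
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' @rdname SignalSet-class
#' @export
setGeneric("eventAnnotations", function(x) standardGeneric("eventAnnotations"))

#' @rdname SignalSet-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname SignalSet-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname ConnectivityResult-class
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' @rdname ConnectivityResult-class
#' @export
setGeneric("sampleCount", function(x) standardGeneric("sampleCount"))

#' @rdname SignalSet-class
#' @export
setGeneric("bandInfo", function(x) standardGeneric("bandInfo"))

#' @rdname ThresholdedNetwork-class
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname GraphMetrics-class
#' @export
setGeneric("nodeMetrics", function(x) standardGeneric("nodeMetrics"))

#' @rdname GraphMetrics-class
#' @export
setGeneric("networkMetrics", function(x) standardGeneric("networkMetrics"))

#' @rdname GraphMetrics-class
#' @export
setGeneric("pathLengthMatrix", function(x, ...) standardGeneric("pathLengthMatrix"))
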