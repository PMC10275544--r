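#' Construct a SignalSet
#'
#' @param data channels x samples numeric matrix.
#' @param samplingRate sampling rate in Hz.
#' @param channels channel metadata data.frame (`label`, `region`,
#'   `hemisphere`); defaults to generated labels with the first half of the
#'   channels tagged anterior and the second half posterior.
#' @param subjectId,group identifiers carried through the pipeline.
#' @param annotations optional event table (`time`, `channel`, `type`).
#' @return a [SignalSet-class] object.
#' @examples
#' x <- SignalSet(matrix(rnorm(400), 4), samplingRate = 100)
#' samplingRate(x)
#' @export
SignalSet <- function(data, samplingRate, channels = NULL,
                      subjectId = "S1", group = "none",
                      annotations = NULL) {
  data <- as.matrix(data)
  if (is.null(channels))
    channels <- defaultChannelMeta(nrow(data))
  new("SignalSet", data = data, samplingRate = as.numeric(samplingRate),
      channels = channels, subjectId = subjectId, group = group,
      annotations = annotations)
}

#' Default channel metadata
#'
#' Labels channels `ch01`, `ch02`, ... and tags the first half anterior /
#' second half posterior, alternating hemispheres. Override by passing an
#' explicit table to [SignalSet()].
#'
#' @param n number of channels.
#' @return data.frame with columns `label`, `region`, `hemisphere`.
#' @export
defaultChannelMeta <- function(n) {
  data.frame(
    label = sprintf("ch%02d", seq_len(n)),
    region = rep(c("anterior", "posterior"), c(ceiling(n / 2), floor(n / 2))),
    hemisphere = rep_len(c("L", "R"), n),
    stringsAsFactors = FALSE
  )
}

#' @rdname SignalSet-class
#' @export
setMethod("signalData", "SignalSet", function(x) x@data)

#' @rdname SignalSet-class
#' @export
setMethod("samplingRate", "SignalSet", function(x) x@samplingRate)

#' @rdname SignalSet-class
#' @export
setMethod("channelInfo", "SignalSet", function(x) x@channels)

#' @rdname SignalSet-class
#' @export
setMethod("eventAnnotations", "SignalSet", function(x) x@annotations)

#' @rdname SignalSet-class
#' @export
setMethod("subjectId", "SignalSet", function(x) x@subjectId)

#' @rdname SignalSet-class
#' @export
setMethod("groupLabel", "SignalSet", function(x) x@group)

setMethod("show", "SignalSet", function(object) {
  cat(sprintf("SignalSet '%s' (group %s): %d channels x %d samples @ %g Hz (%.3g s)\n",
              object@subjectId, object@group, nrow(object@data),
              ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  if (!is.null(object@annotations))
    cat(sprintf("  %d annotated events\n", nrow(object@annotations)))
})

#' @rdname ConnectivityResult-class
#' @export
setMethod("connMatrix", "ConnectivityResult", function(x) x@R)

#' @rdname ConnectivityResult-class
#' @export
setMethod("sampleCount", "ConnectivityResult", function(x) x@K)

#' @rdname SignalSet-class
#' @export
setMethod("bandInfo", "ConnectivityResult", function(x) x@band)

#' @rdname SignalSet-class
#' @export
setMethod("bandInfo", "ThresholdedNetwork", function(x) x@band)

#' @rdname SignalSet-class
#' @export
setMethod("bandInfo", "GraphMetrics", function(x) x@band)

setMethod("show", "ConnectivityResult", function(object) {
  bn <- if (nrow(object@band)) object@band$name[1] else "broadband"
  cat(sprintf("ConnectivityResult '%s' [%s]: %d channels, K = %d samples\n",
              object@subjectId, bn, nrow(object@R), object@K))
  if (length(object@excluded))
    cat(sprintf("  constant channels excluded: %s\n",
                paste(object@excluded, collapse = ", ")))
})

#' @rdname ThresholdedNetwork-class
#' @export
setMethod("edgeWeights", "ThresholdedNetwork", function(x) x@weights)

setMethod("show", "ThresholdedNetwork", function(object) {
  w <- object@weights
  ne <- sum(w[upper.tri(w)] != 0)
  bn <- if (nrow(object@band)) object@band$name[1] else "broadband"
  cat(sprintf(
    "ThresholdedNetwork '%s' [%s]: %d nodes, %d edges (|R| >= %.4f, alpha = %g)\n",
    object@subjectId, bn, nrow(w), ne, object@thresholdR, object@alpha))
  cat(sprintf("  excitatory %d / inhibitory %d\n",
              sum(w[upper.tri(w)] > 0), sum(w[upper.tri(w)] < 0)))
})

#' @rdname GraphMetrics-class
#' @export
setMethod("nodeMetrics", "GraphMetrics", function(x) x@nodes)

#' @rdname GraphMetrics-class
#' @export
setMethod("networkMetrics", "GraphMetrics", function(x) x@network)

#' @rdname GraphMetrics-class
#' @param ... unused.
#' @export
setMethod("pathLengthMatrix", "GraphMetrics", function(x, ...) x@L)

setMethod("show", "GraphMetrics", function(object) {
  bn <- if (nrow(object@band)) object@band$name[1] else "broadband"
  m <- object@network
  cat(sprintf("GraphMetrics '%s' [%s]: DA = %.3f, SA = %.3f, LA = %.3f, CA = %.3f\n",
              object@subjectId, bn, m["DA"], m["SA"], m["LA"], m["CA"]))
})

setMethod("show", "GroupSpec", function(object) {
  cat(sprintf(
    "GroupSpec '%s': %d subjects, spikeRate %g, spikeAmplitude %g, noiseSd %g\n",
    object@name, object@nSubjects, object@spikeRate, object@spikeAmplitude,
    object@noiseSd))
  cat(sprintf("  coupled bands: %s\n",
              if (length(object@coupling)) paste(names(object@coupling),
                                                 collapse = ", ") else "none"))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d groups, %d channels, %g s @ %g Hz, seed %d\n",
              length(object@groups), object@nChannels, object@duration,
              object@samplingRate, object@seed))
  for (g in object@groups) show(g)
})
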