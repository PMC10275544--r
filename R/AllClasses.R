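#' @import methods
NULL

setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' SignalSet: one subject's multichannel recording
#'
#' Container for a channels-by-samples numeric matrix plus the sidecar
#' metadata the connectivity chain needs: sampling rate, channel labels with
#' region/hemisphere tags, subject and group identifiers, and an optional
#' event-annotation table (e.g. injected or marked spikes).
#'
#' @slot data numeric matrix, channels x samples (arbitrary units).
#' @slot samplingRate sampling rate in Hz.
#' @slot channels data.frame with columns `label`, `region`
#'   (`"anterior"`/`"posterior"`), `hemisphere` (`"L"`/`"R"`/`"midline"`);
#'   one row per matrix row.
#' @slot subjectId subject identifier.
#' @slot group group label (e.g. `"IED"`, `"nonIED"`, `"HC"`).
#' @slot annotations `NULL` or data.frame with columns `time` (seconds,
#'   relative to the start of `data`), `channel` (row index) and `type`.
#'
#' @seealso [SignalSet()] for the user constructor.
#' @exportClass SignalSet
setClass("SignalSet",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    channels = "data.frame",
    subjectId = "character",
    group = "character",
    annotations = "data.frameOrNULL"
  )
)

setValidity("SignalSet", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data contains NaN/Inf values")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (nrow(object@channels) != nrow(object@data))
    msg <- c(msg, "channels table must have one row per data row")
  need <- c("label", "region", "hemisphere")
  if (!all(need %in% names(object@channels)))
    msg <- c(msg, sprintf("channels table needs columns %s",
                          paste(need, collapse = ", ")))
  else if (!all(object@channels$region %in% c("anterior", "posterior")))
    msg <- c(msg, "every channel region must be 'anterior' or 'posterior'")
  if (!is.null(object@annotations) &&
      !all(c("time", "channel", "type") %in% names(object@annotations)))
    msg <- c(msg, "annotations need columns time, channel, type")
  if (length(msg)) msg else TRUE
})

#' ConnectivityResult: per-band pairwise correlation matrix
#'
#' Zero-lag Pearson correlation R between every channel pair of a
#' band-filtered [SignalSet], together with the number of samples K that
#' entered each coefficient. Pairs involving a constant (zero-variance)
#' channel are `NA` and are excluded downstream rather than set to 0.
#'
#' @slot R symmetric correlation matrix, unit diagonal, entries in [-1, 1]
#'   or `NA` for excluded pairs.
#' @slot K number of time samples per pair.
#' @slot band one-row data.frame (`name`, `low`, `high`) describing the
#'   analysis band, or a 0-row data.frame for broadband.
#' @slot subjectId,group carried through from the input signals.
#' @slot excluded integer indices of constant channels flagged during
#'   computation.
#'
#' @exportClass ConnectivityResult
setClass("ConnectivityResult",
  representation(
    R = "matrix",
    K = "integer",
    band = "data.frame",
    subjectId = "character",
    group = "character",
    excluded = "integer"
  )
)

setValidity("ConnectivityResult", function(object) {
  msg <- character()
  R <- object@R
  if (nrow(R) != ncol(R)) msg <- c(msg, "R must be square")
  ok <- !is.na(R)
  if (any(abs(R[ok]) > 1 + 1e-12)) msg <- c(msg, "|R| must be <= 1")
  if (!isTRUE(all.equal(R[ok & t(ok)], t(R)[ok & t(ok)], tolerance = 1e-12)))
    msg <- c(msg, "R must be symmetric")
  d <- diag(R)
  if (any(!is.na(d) & abs(d - 1) > 1e-12))
    msg <- c(msg, "diagonal of R must be 1")
  if (object@K < 3L) msg <- c(msg, "K must be >= 3")
  if (length(msg)) msg else TRUE
})

#' ThresholdedNetwork: signed weighted graph surviving the t threshold
#'
#' Edges are correlation coefficients whose t statistic
#' \eqn{T_p = R \sqrt{K-2} / \sqrt{1-R^2}} exceeds the two-sided Student-t
#' critical value at `alpha` with K-2 degrees of freedom. Positive weights
#' are read as excitatory connections, negative as inhibitory; zero means
#' no edge.
#'
#' @slot weights symmetric signed matrix, zero diagonal; nonzero entries
#'   satisfy `abs(w) >= thresholdR`.
#' @slot thresholdR minimal |R| retained.
#' @slot alpha significance level used for the threshold.
#' @slot K sample count behind each correlation.
#' @slot band,subjectId,group provenance from the [ConnectivityResult].
#'
#' @exportClass ThresholdedNetwork
setClass("ThresholdedNetwork",
  representation(
    weights = "matrix",
    thresholdR = "numeric",
    alpha = "numeric",
    K = "integer",
    band = "data.frame",
    subjectId = "character",
    group = "character"
  )
)

setValidity("ThresholdedNetwork", function(object) {
  msg <- character()
  w <- object@weights
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (any(diag(w) != 0)) msg <- c(msg, "diagonal must be zero")
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12)))
    msg <- c(msg, "weights must be symmetric")
  nz <- w[w != 0]
  if (length(nz) && any(abs(nz) < object@thresholdR - 1e-12))
    msg <- c(msg, "nonzero weights must have |w| >= thresholdR")
  if (length(msg)) msg else TRUE
})

#' GraphMetrics: weighted topology summary of one network
#'
#' Node-level degree \eqn{d_i}, strength \eqn{S_i} and clustering
#' coefficient \eqn{C_i}, the shortest-path-length matrix \eqn{L_{ij}}
#' (inverse-weight edge lengths, 0 for unreachable pairs and the diagonal),
#' and the network averages DA, SA, LA, CA.
#'
#' @slot nodes data.frame with columns `node`, `degree`, `strength`,
#'   `clustering`.
#' @slot L shortest-path-length matrix.
#' @slot network named numeric vector `c(DA=, SA=, LA=, CA=)`.
#' @slot band,subjectId,group provenance.
#'
#' @exportClass GraphMetrics
setClass("GraphMetrics",
  representation(
    nodes = "data.frame",
    L = "matrix",
    network = "numeric",
    band = "data.frame",
    subjectId = "character",
    group = "character"
  )
)

setValidity("GraphMetrics", function(object) {
  msg <- character()
  if (!all(c("DA", "SA", "LA", "CA") %in% names(object@network)))
    msg <- c(msg, "network vector needs DA, SA, LA, CA")
  n <- nrow(object@nodes)
  if (n && any(object@nodes$degree < 0 | object@nodes$degree > n - 1))
    msg <- c(msg, "degrees must lie in [0, N-1]")
  if (length(msg)) msg else TRUE
})

#' GroupSpec: generative recipe for one synthetic group
#'
#' @slot name group label.
#' @slot nSubjects number of subjects to generate.
#' @slot coupling named list (one entry per band name) of symmetric
#'   coupling matrices: target pairwise correlations in [0, 1), zero
#'   diagonal. Bands without an entry get independent sources.
#' @slot spikeRate expected spike-wave events per analysis window
#'   (Poisson mean; 0 disables injection).
#' @slot spikeAmplitude spike peak as a multiple of the background RMS.
#' @slot noiseSd white sensor-noise SD relative to the signal RMS.
#'
#' @exportClass GroupSpec
setClass("GroupSpec",
  representation(
    name = "character",
    nSubjects = "integer",
    coupling = "list",
    spikeRate = "numeric",
    spikeAmplitude = "numeric",
    noiseSd = "numeric"
  )
)

setValidity("GroupSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 0L) msg <- c(msg, "nSubjects must be >= 0")
  if (object@spikeRate < 0) msg <- c(msg, "spikeRate must be >= 0")
  if (object@spikeAmplitude < 0) msg <- c(msg, "spikeAmplitude must be >= 0")
  for (nm in names(object@coupling)) {
    cm <- object@coupling[[nm]]
    if (!is.matrix(cm) || nrow(cm) != ncol(cm)) {
      msg <- c(msg, sprintf("coupling[[%s]] must be a square matrix", nm))
      next
    }
    if (any(abs(cm - t(cm)) > 1e-12))
      msg <- c(msg, sprintf("coupling[[%s]] must be symmetric", nm))
    if (any(diag(cm) != 0))
      msg <- c(msg, sprintf("coupling[[%s]] must have zero diagonal", nm))
    if (any(cm < 0) || any(cm >= 1))
      msg <- c(msg, sprintf("coupling[[%s]] entries must lie in [0, 1)", nm))
  }
  if (length(msg)) msg else TRUE
})

#' CohortSpec: full generative recipe for a synthetic cohort
#'
#' @slot groups list of [GroupSpec-class] objects with distinct names.
#' @slot samplingRate Hz; must be at least twice the highest band edge.
#' @slot duration seconds per subject window.
#' @slot nChannels channel count (matches coupling matrix dimensions).
#' @slot bands band table as from [defaultBands()].
#' @slot seed master seed; per-subject seeds are derived from it.
#'
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    groups = "list",
    samplingRate = "numeric",
    duration = "numeric",
    nChannels = "integer",
    bands = "data.frame",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@nChannels < 2L) msg <- c(msg, "nChannels must be >= 2")
  nms <- vapply(object@groups, function(g) g@name, character(1))
  if (anyDuplicated(nms)) msg <- c(msg, "duplicate group names")
  if (nrow(object@bands) &&
      object@samplingRate < 2 * max(object@bands$high))
    msg <- c(msg, sprintf(
      "samplingRate %g below twice the highest band edge (%g Hz)",
      object@samplingRate, max(object@bands$high)))
  for (g in object@groups) {
    for (nm in names(g@coupling)) {
      if (!nm %in% object@bands$name)
        msg <- c(msg, sprintf("group %s couples unknown band '%s'",
                              g@name, nm))
      else if (nrow(g@coupling[[nm]]) != object@nChannels)
        msg <- c(msg, sprintf(
          "group %s coupling[[%s]] dimension != nChannels", g@name, nm))
    }
  }
  if (length(msg)) msg else TRUE
})
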