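# Plain-text containers: signals as a CSV matrix (channels x samples)
# with a JSON sidecar for the metadata; networks as tidy edge-list TSV;
# tables as CSV. Everything round-trips.

#' Write a SignalSet to disk
#'
#' Writes `<prefix>_data.csv` (channels x samples, no header) and
#' `<prefix>_meta.json` (sampling rate, channel table, subject, group,
#' annotations).
#'
#' @param signals a [SignalSet-class].
#' @param prefix path prefix for the two files.
#' @return the two file paths, invisibly.
#' @export
writeSignalSet <- function(signals, prefix) {
  dataPath <- paste0(prefix, "_data.csv")
  metaPath <- paste0(prefix, "_meta.json")
  utils::write.table(signalData(signals), dataPath, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    sampling_rate = samplingRate(signals),
    subject_id = subjectId(signals),
    group = groupLabel(signals),
    channels = channelInfo(signals),
    annotations = eventAnnotations(signals)
  )
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(dataPath, metaPath))
}

#' Read a SignalSet written by [writeSignalSet()]
#'
#' @param prefix the path prefix used when writing.
#' @return a [SignalSet-class].
#' @export
readSignalSet <- function(prefix) {
  dataPath <- paste0(prefix, "_data.csv")
  metaPath <- paste0(prefix, "_meta.json")
  x <- as.matrix(utils::read.table(dataPath, sep = ",", header = FALSE))
  dimnames(x) <- NULL
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  ann <- meta$annotations
  if (!is.null(ann) && length(ann) && nrow(as.data.frame(ann)))
    ann <- as.data.frame(ann)
  else ann <- NULL
  SignalSet(x, meta$sampling_rate, channels = as.data.frame(meta$channels),
            subjectId = meta$subject_id, group = meta$group,
            annotations = ann)
}

#' Write a thresholded network as a tidy edge list
#'
#' TSV with columns `source`, `target`, `R`, `sign`; one row per surviving
#' (upper-triangle) edge.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param path output file.
#' @export
writeEdgeList <- function(net, path) {
  w <- edgeWeights(net)
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  df <- data.frame(source = idx[, 1], target = idx[, 2],
                   R = w[idx],
                   sign = ifelse(w[idx] > 0, "excitatory", "inhibitory"))
  df <- df[order(df$source, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cognitive-score table
#'
#' CSV with columns `subject_id`, `FSIQ`, `VCI`, `PRI`, `WMI`, `PSI`
#' (a `group` column is allowed and preserved). Scores at or below 80
#' FSIQ raise a warning, not an error: inclusion thresholds are a data
#' property.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
readScores <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "FSIQ", "VCI", "PRI", "WMI", "PSI")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("score table missing column(s): %s",
                 paste(miss, collapse = ", ")))
  sc <- as.matrix(df[, c("FSIQ", "VCI", "PRI", "WMI", "PSI")])
  if (any(sc <= 0)) stop("scores must be positive")
  if (any(df$FSIQ <= 80))
    warning(sprintf("%d subject(s) with FSIQ <= 80", sum(df$FSIQ <= 80)))
  df
}
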