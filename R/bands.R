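#' Canonical frequency-band scheme
#'
#' The six analysis bands used throughout: delta 1-4, theta 4-8, alpha
#' 8-12, beta 12-30, gamma 30-80 and ripple 80-250 Hz. Band intervals are
#' treated as half-open `[low, high)` so shared edges are not
#' double-counted (4 Hz belongs to theta, not delta).
#'
#' @return data.frame with columns `name`, `low`, `high` (Hz).
#' @examples
#' defaultBands()
#' @export
defaultBands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma", "ripple"),
    low = c(1, 4, 8, 12, 30, 80),
    high = c(4, 8, 12, 30, 80, 250),
    stringsAsFactors = FALSE
  )
}

#' Build a one-row band definition
#'
#' @param name band label.
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return one-row data.frame compatible with [defaultBands()].
#' @export
bandDefinition <- function(name, low, high) {
  if (!(low > 0 && high > low))
    stop("band edges must satisfy 0 < low < high")
  data.frame(name = name, low = low, high = high, stringsAsFactors = FALSE)
}

.checkBandVsRate <- function(band, fs) {
  if (band$high >= fs / 2)
    stop(sprintf("band '%s' top edge %g Hz is at or above Nyquist (%g Hz)",
                 band$name, band$high, fs / 2))
  invisible(TRUE)
}
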