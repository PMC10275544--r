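# Pairwise zero-lag correlation and the t-statistic edge threshold.
#
# The connection test works on the t transform of a correlation,
#   Tp = R * sqrt(K - 2) / sqrt(1 - R^2),
# which under the null follows Student's t with K - 2 degrees of freedom;
# edges whose two-sided p-value is below alpha survive, keeping their sign
# (positive = excitatory, negative = inhibitory).

#' Pairwise zero-lag correlation of all channel pairs
#'
#' Computes the Pearson product-moment correlation between every pair of
#' channels over the analysis window. Constant (zero-variance) channels
#' are flagged and their pairs set to `NA` — undefined and excluded
#' downstream, never coerced to 0.
#'
#' @param signals a [SignalSet-class] (typically already band-filtered).
#' @param band optional one-row band table recorded as provenance.
#' @return a [ConnectivityResult-class] with the correlation matrix `R`
#'   and the per-pair sample count `K` (the window length in samples).
#' @examples
#' x <- SignalSet(matrix(rnorm(3 * 500), 3), samplingRate = 100)
#' conn <- pairwiseCorrelation(x)
#' connMatrix(conn)[1, 2]
#' @export
pairwiseCorrelation <- function(signals, band = NULL) {
  x <- signalData(signals)
  if (nrow(x) < 2L) stop("need at least 2 channels")
  K <- ncol(x)
  if (K < 3L) stop("need at least 3 samples")
  sds <- apply(x, 1L, stats::sd)
  excluded <- which(sds == 0)
  if (length(excluded))
    warning(sprintf("constant channel(s) excluded from correlation: %s",
                    paste(excluded, collapse = ", ")))
  R <- suppressWarnings(stats::cor(t(x)))
  R[excluded, ] <- NA_real_
  R[, excluded] <- NA_real_
  R <- (R + t(R)) / 2   # enforce exact symmetry against rounding
  d <- rep(1, nrow(x))
  d[excluded] <- NA_real_
  diag(R) <- d
  if (is.null(band)) band <- data.frame(name = character(0),
                                        low = numeric(0), high = numeric(0))
  new("ConnectivityResult", R = R, K = as.integer(K), band = band,
      subjectId = subjectId(signals), group = groupLabel(signals),
      excluded = as.integer(excluded))
}

#' Critical correlation magnitude for the t threshold
#'
#' Inverts the t transform of a correlation coefficient: returns the |R|
#' at which \eqn{T_p = R\sqrt{K-2}/\sqrt{1-R^2}} equals the two-sided
#' Student-t critical value with `K - 2` degrees of freedom at level
#' `alpha`. Monotonically decreasing in `K`.
#'
#' @param K number of data points per pair (>= 3).
#' @param alpha two-sided significance level in (0, 1); default 0.05.
#' @return threshold correlation magnitude in (0, 1).
#' @examples
#' criticalR(30000)   # long windows admit small correlations
#' criticalR(300)
#' @export
criticalR <- function(K, alpha = 0.05) {
  if (any(K < 3L)) stop("K must be >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  tcrit <- stats::qt(1 - alpha / 2, df = K - 2)
  tcrit / sqrt(K - 2 + tcrit^2)
}

#' t statistic of a correlation coefficient
#'
#' @param R correlation coefficient(s), |R| < 1.
#' @param K number of data points.
#' @return `R * sqrt(K - 2) / sqrt(1 - R^2)`.
#' @export
correlationT <- function(R, K) {
  R * sqrt(K - 2) / sqrt(1 - R^2)
}

#' Threshold a connectivity matrix into a signed network
#'
#' Retains the pairs whose correlation magnitude reaches the critical
#' value from [criticalR()] at level `alpha` (equivalently, whose
#' per-pair two-sided t-test is significant). Retained weights keep the
#' sign and magnitude of `R`; the diagonal is removed. `NA` pairs
#' (excluded channels) never form edges.
#'
#' @param conn a [ConnectivityResult-class].
#' @param alpha two-sided edge significance level (default 0.05).
#' @return a [ThresholdedNetwork-class].
#' @export
buildNetwork <- function(conn, alpha = 0.05) {
  R <- connMatrix(conn)
  thr <- criticalR(sampleCount(conn), alpha)
  w <- R
  w[is.na(w)] <- 0
  w[abs(w) < thr] <- 0
  diag(w) <- 0
  new("ThresholdedNetwork", weights = w, thresholdR = thr, alpha = alpha,
      K = sampleCount(conn), band = bandInfo(conn),
      subjectId = conn@subjectId, group = conn@group)
}

#' Count edges by anterior/posterior region pair
#'
#' Splits the surviving edges into anterior-anterior, anterior-posterior
#' and posterior-posterior counts; the three always sum to the total edge
#' count. Used to quantify long-range (anterior-posterior) connectivity
#' differences between groups.
#'
#' @param net a [ThresholdedNetwork-class].
#' @param channels channel metadata with a `region` column (one row per
#'   node).
#' @return named numeric vector
#'   `c(anterior_anterior=, anterior_posterior=, posterior_posterior=)`.
#' @export
regionalEdgeCount <- function(net, channels) {
  w <- edgeWeights(net)
  if (nrow(channels) != nrow(w))
    stop("channel metadata does not match network size")
  region <- channels$region
  if (is.null(region) || any(!region %in% c("anterior", "posterior")))
    stop("every channel needs an 'anterior' or 'posterior' region tag")
  counts <- c(anterior_anterior = 0, anterior_posterior = 0,
              posterior_posterior = 0)
  idx <- which(upper.tri(w) & w != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    ri <- region[idx[k, 1]]
    rj <- region[idx[k, 2]]
    key <- if (ri == rj) paste0(ri, "_", ri) else "anterior_posterior"
    counts[key] <- counts[key] + 1
  }
  counts
}
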