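# Independent brute-force oracles for the weighted graph metrics, kept
# deliberately naive: Floyd-Warshall on inverse-weight edge lengths and
# exhaustive triangle enumeration. They share no code with the package
# implementations.

fwPathOracle <- function(w) {
  n <- nrow(w)
  D <- ifelse(w > 0, 1 / w, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D[is.infinite(D)] <- 0
  diag(D) <- 0
  D
}

clusteringOracle <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  wn <- if (mx > 0) w / mx else w
  d <- rowSums(w > 0)
  C <- numeric(n)
  for (i in seq_len(n)) {
    if (d[i] < 2) next
    s <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j == i || k == i || j == k) next
      s <- s + (wn[i, j] * wn[j, k] * wn[k, i])^(1 / 3)
    }
    C[i] <- s / (d[i] * (d[i] - 1))
  }
  C
}

degreeOracle <- function(w) apply(w, 1, function(r) sum(r > 0))

strengthOracle <- function(w) rowSums(w) / nrow(w)

randomWeightedGraph <- function(n, density = 0.5) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[stats::runif(length(up)) < density]
  w[on] <- stats::runif(length(on), 0.05, 1)
  w + t(w)
}

# Tiny two-channel subject with a planted theta-band correlation.
plantedPair <- function(r, duration = 20, fs = 1000, seed = 1,
                        noiseSd = 0.05, band = "theta") {
  cm <- matrix(c(0, r, r, 0), 2)
  coupling <- list()
  coupling[[band]] <- cm
  g <- groupSpec("pair", nSubjects = 1L, coupling = coupling,
                 noiseSd = noiseSd)
  generateSubject(g, defaultBands(), fs, duration, 2L, seed = seed)
}

sineSignal <- function(freq, fs = 1000, duration = 30, nChannels = 1L) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  SignalSet(matrix(rep(sin(2 * pi * freq * t), nChannels),
                   nrow = nChannels, byrow = TRUE), fs)
}

coreRms <- function(x, frac = 0.6) {
  n <- length(x)
  i <- round(n * (1 - frac) / 2)
  sqrt(mean(x[(i + 1):(n - i)]^2))
}
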