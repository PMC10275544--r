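# Synthetic cohorts: band-limited Gaussian sources with planted pairwise
# correlation, optional spike-and-slow-wave transients, additive white
# sensor noise. Everything is seeded and bit-reproducible.

#' Specify one synthetic group
#'
#' @param name group label (conventionally `"IED"`, `"nonIED"`, `"HC"`,
#'   but any label works).
#' @param nSubjects subjects to generate (default 15 per group).
#' @param coupling named list of per-band symmetric target-correlation
#'   matrices (entries in `[0, 1)`, zero diagonal). Bands without an entry
#'   get mutually independent sources.
#' @param spikeRate expected spike-wave events per window (Poisson mean);
#'   default 0. An IED-like group uses about 10 per 30-s window.
#' @param spikeAmplitude spike peak as a multiple of the channel RMS.
#' @param noiseSd white-noise SD relative to the summed band-signal RMS.
#' @return a [GroupSpec-class].
#' @export
groupSpec <- function(name, nSubjects = 15L, coupling = list(),
                      spikeRate = 0, spikeAmplitude = 6, noiseSd = 0.1) {
  new("GroupSpec", name = name, nSubjects = as.integer(nSubjects),
      coupling = coupling, spikeRate = spikeRate,
      spikeAmplitude = spikeAmplitude, noiseSd = noiseSd)
}

#' Specify a synthetic cohort
#'
#' @param groups list of [groupSpec()] objects with distinct names.
#' @param samplingRate Hz; must be at least twice the top band edge
#'   (>= 500 Hz when the ripple band is in use). Default 1000.
#' @param duration window length in seconds (default 30, the single
#'   analysis window the connectivity chain consumes).
#' @param nChannels number of virtual-sensor channels (default 30).
#' @param bands band table; default [defaultBands()].
#' @param seed master seed; per-subject seeds derive from it.
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(groups, samplingRate = 1000, duration = 30,
                       nChannels = 30L, bands = defaultBands(), seed = 1L) {
  new("CohortSpec", groups = groups, samplingRate = samplingRate,
      duration = duration, nChannels = as.integer(nChannels),
      bands = bands, seed = as.integer(seed))
}

#' Default three-group cohort
#'
#' Builds the stated world the analysis chain is exercised on: three
#' groups of 15 subjects (IED, nonIED, HC), 30 channels (first half
#' anterior, second half posterior), a 30-s window at 1000 Hz, six bands.
#' All groups share moderate within-region coupling (r = 0.35) in every
#' band; long-range anterior-posterior coupling in the beta and ripple
#' bands is graded HC (0.30) > nonIED (0.18) > IED (0.08), and the IED
#' group carries ~10 spike-wave events per window. See the methods
#' vignette for the reasoning behind these defaults.
#'
#' @param nSubjects subjects per group.
#' @param nChannels channels per subject.
#' @param samplingRate,duration window geometry.
#' @param seed master seed.
#' @return a [CohortSpec-class].
#' @export
defaultCohortSpec <- function(nSubjects = 15L, nChannels = 30L,
                              samplingRate = 1000, duration = 30,
                              seed = 1L) {
  bands <- defaultBands()
  longRange <- c(IED = 0.08, nonIED = 0.18, HC = 0.30)
  mk <- function(within, between, n) {
    half <- ceiling(n / 2)
    blk <- c(rep(1L, half), rep(2L, n - half))
    cm <- ifelse(outer(blk, blk, "=="), within, between)
    diag(cm) <- 0
    cm
  }
  groups <- lapply(names(longRange), function(g) {
    coupling <- list()
    for (b in bands$name) {
      between <- if (b %in% c("beta", "ripple")) longRange[[g]] else 0.10
      coupling[[b]] <- mk(0.35, between, nChannels)
    }
    groupSpec(g, nSubjects = nSubjects, coupling = coupling,
              spikeRate = if (g == "IED") 10 else 0)
  })
  cohortSpec(groups, samplingRate = samplingRate, duration = duration,
             nChannels = nChannels, bands = bands, seed = seed)
}

# Target correlation matrix -> mixing matrix via Cholesky. For a single
# coupled pair this reduces to sharing a latent source at weight sqrt(r).
.mixingFromCoupling <- function(coupling) {
  C <- coupling
  diag(C) <- 1
  ch <- tryCatch(chol(C), error = function(e)
    stop("coupling matrix does not define a positive-definite correlation ",
         "structure; reduce coupling strengths"))
  t(ch)
}

# |H(f)|^2 of a biquad cascade on a frequency grid.
.sosPowerResponse <- function(sos, f, fs) {
  w <- 2 * pi * f / fs
  e1 <- exp(-1i * w)
  e2 <- exp(-2i * w)
  h2 <- rep(1, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[s, 1] + sos[s, 2] * e1 + sos[s, 3] * e2
    den <- 1 + sos[s, 5] * e1 + sos[s, 6] * e2
    h2 <- h2 * (Mod(num)^2 / Mod(den)^2)
  }
  h2
}

# Cross-band leakage of the generation/measurement filters. A[b, b'] is
# the fraction of the correlation planted in band b' that shows up when
# band b is measured: adjacent band components pass partially through a
# band's transition region and dilute (or contaminate) the estimate.
# Planting latent correlations r = solve(A, target) makes the expected
# band-filtered correlation equal the target exactly.
.bandLeakageMatrix <- function(bands, fs, noiseSd, nGrid = 8192L) {
  f <- seq(0, fs / 2, length.out = nGrid)
  nb <- nrow(bands)
  H4 <- matrix(0, nb, nGrid)   # filtfilt power response |H|^4 per band
  for (i in seq_len(nb)) {
    sos <- .butterBandpassSos(bands$low[i], bands$high[i], fs)
    H4[i, ] <- .sosPowerResponse(sos, f, fs)^2
  }
  P <- matrix(0, nb, nb)       # P[b', b]: unit-var component b' through filter b
  for (bp in seq_len(nb)) {
    psd <- H4[bp, ] / sum(H4[bp, ])
    P[bp, ] <- as.numeric(H4 %*% psd)
  }
  noiseVar <- noiseSd^2 * nb   # white noise relative to summed band RMS
  Tb <- colSums(P) + noiseVar * rowMeans(H4)
  t(P) / Tb
}

# Solve for the per-band latent correlation matrices that reproduce the
# user's targets through the band-filtered measurement chain.
.latentCoupling <- function(group, bands, fs, nChannels) {
  nb <- nrow(bands)
  targets <- lapply(seq_len(nb), function(i) {
    cm <- group@coupling[[bands$name[i]]]
    if (is.null(cm)) matrix(0, nChannels, nChannels) else cm
  })
  if (all(vapply(targets, function(m) all(m == 0), logical(1))))
    return(NULL)
  Ainv <- solve(.bandLeakageMatrix(bands, fs, group@noiseSd))
  latent <- lapply(seq_len(nb), function(b) {
    m <- matrix(0, nChannels, nChannels)
    for (bp in seq_len(nb)) m <- m + Ainv[b, bp] * targets[[bp]]
    m
  })
  for (b in seq_len(nb)) {
    if (any(abs(latent[[b]]) >= 1))
      stop(sprintf(
        "coupling in band '%s' too strong once band leakage is compensated",
        bands$name[b]))
  }
  names(latent) <- bands$name
  latent
}

# Circularly filtered white noise: exactly stationary band-limited
# Gaussian sources, standardised to unit sample variance per channel.
.bandLimitedNoise <- function(nChannels, nSamples, band, fs) {
  z <- matrix(stats::rnorm(nChannels * nSamples), nrow = nChannels)
  sos <- .butterBandpassSos(band$low, band$high, fs)
  z <- .circularFilterMatrix(z, sos, fs)
  sdz <- apply(z, 1L, stats::sd)
  z / sdz
}

#' Generate one synthetic subject
#'
#' For each band, independent unit-variance band-limited Gaussian sources
#' are mixed through the Cholesky factor of the band's target correlation
#' matrix, so the expected pairwise correlation of the band-filtered
#' channels equals the planted coupling entry. Band components are summed
#' and white sensor noise is added at `noiseSd` relative to the signal
#' RMS. Spike-wave transients (if `spikeRate > 0`) are injected last.
#'
#' @param group a [groupSpec()].
#' @param bands band table (all bands generated, coupled or not).
#' @param samplingRate,duration,nChannels window geometry.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param subjectId,channels forwarded to the [SignalSet()].
#' @return a [SignalSet-class] (with spike annotations when injected).
#' @examples
#' g <- groupSpec("demo", coupling = list(
#'   theta = matrix(c(0, .6, .6, 0), 2)), noiseSd = 0.05)
#' s <- generateSubject(g, defaultBands()[1:4, ], samplingRate = 250,
#'                      duration = 8, nChannels = 2, seed = 7)
#' @export
generateSubject <- function(group, bands, samplingRate, duration,
                            nChannels, seed, subjectId = "S1",
                            channels = NULL) {
  for (nm in names(group@coupling)) {
    if (!nm %in% bands$name)
      stop(sprintf("coupling refers to unknown band '%s'", nm))
    if (nrow(group@coupling[[nm]]) != nChannels)
      stop(sprintf("coupling[[%s]] dimension != nChannels", nm))
  }
  for (i in seq_len(nrow(bands))) {
    if (samplingRate < 2 * bands$high[i])
      stop(sprintf("sampling rate %g Hz aliases band '%s' (top edge %g Hz)",
                   samplingRate, bands$name[i], bands$high[i]))
  }
  latent <- .latentCoupling(group, bands, samplingRate, nChannels)
  set.seed(as.integer(seed))
  ns <- round(duration * samplingRate)
  x <- matrix(0, nChannels, ns)
  for (i in seq_len(nrow(bands))) {
    band <- bands[i, ]
    z <- .bandLimitedNoise(nChannels, ns, band, samplingRate)
    if (!is.null(latent) && any(latent[[band$name]] != 0))
      z <- .mixingFromCoupling(latent[[band$name]]) %*% z
    x <- x + z
  }
  if (group@noiseSd > 0) {
    rms <- sqrt(mean(x^2))
    x <- x + matrix(stats::rnorm(nChannels * ns, sd = group@noiseSd * rms),
                    nChannels, ns)
  }
  out <- SignalSet(x, samplingRate, channels = channels,
                   subjectId = subjectId, group = group@name)
  if (group@spikeRate > 0)
    out <- injectSpikes(out, group@spikeRate, group@spikeAmplitude,
                        seed = as.integer(seed) + 1L)
  out
}

# Biphasic sharp transient (~70 ms) followed by a slower wave of opposite
# polarity (~200 ms): the classic spike-and-slow-wave morphology.
.spikeTemplate <- function(fs, widthScale = 1) {
  nSpike <- max(4L, round(0.070 * widthScale * fs))
  nWave <- max(4L, round(0.200 * widthScale * fs))
  spike <- sin(2 * pi * seq(0, 1, length.out = nSpike))     # sharp biphasic
  wave <- -0.4 * sin(pi * seq(0, 1, length.out = nWave))    # slow wave
  c(spike, wave)
}

#' Inject spike-and-slow-wave transients
#'
#' Draws a Poisson(`spikeRate`) number of events, places them uniformly in
#' the window on uniformly chosen channels and adds a spike-and-slow-wave
#' template scaled to `spikeAmplitude` times that channel's RMS, with
#' +/-10% random jitter in amplitude and width. Signal length and channel
#' count are unchanged; injected events are recorded in the annotation
#' table (the ground truth available to tests).
#'
#' @param signals a [SignalSet-class].
#' @param spikeRate Poisson mean event count for the window (>= 0;
#'   0 returns the input unchanged, with an empty annotation table).
#' @param spikeAmplitude peak amplitude in channel-RMS multiples.
#' @param seed integer seed.
#' @return a [SignalSet-class] whose annotations list the injected events.
#' @export
injectSpikes <- function(signals, spikeRate, spikeAmplitude, seed = 1L) {
  if (spikeRate < 0) stop("spikeRate must be >= 0")
  if (spikeAmplitude < 0) stop("spikeAmplitude must be >= 0")
  empty <- data.frame(time = numeric(0), channel = integer(0),
                      type = character(0), stringsAsFactors = FALSE)
  if (spikeRate == 0)
    return(initialize(signals, annotations = empty))
  set.seed(as.integer(seed))
  fs <- samplingRate(signals)
  x <- signalData(signals)
  ns <- ncol(x)
  nEvents <- stats::rpois(1L, spikeRate)
  ann <- empty
  maxLen <- length(.spikeTemplate(fs, 1.1))
  for (e in seq_len(nEvents)) {
    ch <- sample.int(nrow(x), 1L)
    t0 <- sample.int(max(1L, ns - maxLen), 1L)
    ampJit <- stats::runif(1, 0.9, 1.1)
    widJit <- stats::runif(1, 0.9, 1.1)
    tpl <- .spikeTemplate(fs, widJit)
    rms <- sqrt(mean(x[ch, ]^2))
    idx <- t0:min(ns, t0 + length(tpl) - 1L)
    x[ch, idx] <- x[ch, idx] +
      spikeAmplitude * ampJit * rms * tpl[seq_along(idx)]
    ann <- rbind(ann, data.frame(time = (t0 - 1) / fs, channel = ch,
                                 type = "spike", stringsAsFactors = FALSE))
  }
  initialize(signals, data = x, annotations = ann)
}

.deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) * 10007 + index * 101) %% 2147483629)
}

#' Generate a full synthetic cohort
#'
#' One [SignalSet-class] per subject per group, each generated from a seed
#' derived deterministically from the master seed, so the same spec and
#' seed reproduce the cohort bit-identically.
#'
#' @param spec a [cohortSpec()].
#' @return list with elements `subjects` (list of [SignalSet-class]) and
#'   `groundTruth` (the cohort specification plus per-subject seeds and spike
#'   annotations).
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  subjects <- list()
  seeds <- integer(0)
  idx <- 0L
  for (g in spec@groups) {
    validObject(g)
    for (j in seq_len(g@nSubjects)) {
      idx <- idx + 1L
      sid <- sprintf("%s_%02d", g@name, j)
      sd <- .deriveSeed(spec@seed, idx)
      subjects[[sid]] <- generateSubject(
        g, spec@bands, spec@samplingRate, spec@duration, spec@nChannels,
        seed = sd, subjectId = sid)
      seeds[sid] <- sd
    }
  }
  annotations <- lapply(subjects, eventAnnotations)
  list(subjects = subjects,
       groundTruth = list(spec = spec, subjectSeeds = seeds,
                          spikeAnnotations = annotations))
}

#' Simulate WISC-IV-style cognitive scores
#'
#' Draws per-subject FSIQ/VCI/PRI/WMI/PSI scores from group-specific
#' normal distributions. The default means and SDs follow the group-level
#' summaries typical for an IED / nonIED / HC comparison in this
#' population (IED lowest on FSIQ, VCI and WMI); any matrix of means/SDs
#' with groups as rows can be supplied.
#'
#' @param subjects character vector of subject ids, or the `subjects` list
#'   from [generateCohort()].
#' @param groups group label per subject (taken from the SignalSets when a
#'   cohort list is given).
#' @param means,sds numeric matrices (group x score) with rownames naming
#'   the groups and colnames `FSIQ, VCI, PRI, WMI, PSI`.
#' @param seed integer seed.
#' @return data.frame with columns `subject_id`, `group`, `FSIQ`, `VCI`,
#'   `PRI`, `WMI`, `PSI`.
#' @export
simulateScores <- function(subjects, groups = NULL,
                           means = defaultScoreMeans(),
                           sds = defaultScoreSds(), seed = 1L) {
  if (is.list(subjects) && !is.null(subjects[[1]]) &&
      methods::is(subjects[[1]], "SignalSet")) {
    groups <- vapply(subjects, groupLabel, character(1))
    subjects <- vapply(subjects, subjectId, character(1))
  }
  stopifnot(length(subjects) == length(groups))
  unknown <- setdiff(unique(groups), rownames(means))
  if (length(unknown))
    stop(sprintf("no score distribution for group(s): %s",
                 paste(unknown, collapse = ", ")))
  set.seed(as.integer(seed))
  scores <- t(vapply(groups, function(g) {
    stats::rnorm(ncol(means), means[g, ], sds[g, ])
  }, numeric(ncol(means))))
  out <- data.frame(subject_id = subjects, group = groups,
                    round(scores, 1), stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- colnames(means)
  rownames(out) <- NULL
  low <- out$FSIQ <= 80
  if (any(low))
    warning(sprintf("%d subject(s) with FSIQ <= 80", sum(low)))
  out
}

#' @rdname simulateScores
#' @export
defaultScoreMeans <- function() {
  m <- rbind(
    IED = c(95.53, 87.53, 105.06, 92.27, 103.67),
    nonIED = c(102.73, 100.00, 108.80, 99.33, 99.20),
    HC = c(111.67, 114.53, 108.87, 105.40, 101.73))
  colnames(m) <- c("FSIQ", "VCI", "PRI", "WMI", "PSI")
  m
}

#' @rdname simulateScores
#' @export
defaultScoreSds <- function() {
  m <- rbind(
    IED = c(6.37, 10.82, 8.67, 8.79, 12.99),
    nonIED = c(11.49, 14.56, 13.26, 12.27, 10.11),
    HC = c(12.21, 12.42, 12.02, 10.29, 12.03))
  colnames(m) <- c("FSIQ", "VCI", "PRI", "WMI", "PSI")
  m
}
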