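test_that("generation is deterministic under a fixed seed", {
  g <- groupSpec("g", coupling = list(theta = matrix(c(0, .5, .5, 0), 2)),
                 noiseSd = 0.1)
  a <- generateSubject(g, defaultBands(), 1000, 4, 2, seed = 11)
  b <- generateSubject(g, defaultBands(), 1000, 4, 2, seed = 11)
  expect_identical(signalData(a), signalData(b))

  spec <- cohortSpec(list(groupSpec("A", 2L), groupSpec("B", 2L)),
                     samplingRate = 1000, duration = 2, nChannels = 3L,
                     seed = 5L)
  c1 <- generateCohort(spec)
  c2 <- generateCohort(spec)
  expect_identical(lapply(c1$subjects, signalData),
                   lapply(c2$subjects, signalData))
})

test_that("uncoupled channels show only sampling-level correlation", {
  g <- groupSpec("null", nSubjects = 1L, noiseSd = 0.1)
  s <- generateSubject(g, defaultBands(), 1000, 30, 6, seed = 21)
  for (i in c(2, 4)) {   # theta and beta
    band <- defaultBands()[i, ]
    R <- connMatrix(pairwiseCorrelation(bandpassFilter(s, band)))
    off <- abs(R[upper.tri(R)])
    neff <- effectiveSampleCount(band, 1000, 30)
    expect_lt(mean(off), 3 / sqrt(neff))
  }
})

test_that("a planted theta correlation is recovered through the chain", {
  # target 0.8 between the two channels, 60 s at 1000 Hz
  s <- plantedPair(0.8, duration = 60, seed = 42)
  th <- bandpassFilter(s, defaultBands()[2, ])
  expect_equal(connMatrix(pairwiseCorrelation(th))[1, 2], 0.8,
               tolerance = 0.05 / 0.8)
})

test_that("coupling planted in one band stays out of disjoint bands", {
  s <- plantedPair(0.8, duration = 60, seed = 7)
  for (i in c(1, 3, 4, 5)) {
    R <- connMatrix(pairwiseCorrelation(bandpassFilter(s,
                                                       defaultBands()[i, ])))
    expect_lt(abs(R[1, 2]), 0.1)
  }
})

test_that("invalid specs are rejected", {
  expect_error(groupSpec("bad", coupling = list(
    theta = matrix(c(0, 1, 1, 0), 2))), "\\[0, 1\\)")
  expect_error(groupSpec("bad", coupling = list(
    theta = matrix(c(0.5, .2, .2, 0.5), 2))), "diagonal")
  g <- groupSpec("g", coupling = list(ripple = matrix(0, 2, 2)))
  expect_error(generateSubject(g, defaultBands(), 400, 2, 2, seed = 1),
               "aliases")
  expect_error(cohortSpec(list(groupSpec("A"), groupSpec("A")),
                          nChannels = 30L, seed = 1L), "duplicate")
})

test_that("spike injection: rate 0 is the identity, counts are Poisson", {
  g <- groupSpec("g", nSubjects = 1L, noiseSd = 0)
  s <- generateSubject(g, defaultBands()[1:4, ], 250, 4, 2, seed = 3)
  s0 <- injectSpikes(s, 0, 6)
  expect_identical(signalData(s0), signalData(s))
  expect_identical(nrow(eventAnnotations(s0)), 0L)

  counts <- vapply(seq_len(500), function(k) {
    nrow(eventAnnotations(injectSpikes(s, 10, 6, seed = 1000 + k)))
  }, numeric(1))
  expect_equal(mean(counts), 10, tolerance = 0.5 / 10)
})

test_that("spike amplitude dominates the background signal", {
  g <- groupSpec("g", nSubjects = 1L, noiseSd = 0.05)
  s <- generateSubject(g, defaultBands()[1:4, ], 250, 30, 2, seed = 9)
  sp <- injectSpikes(s, 10, 8, seed = 17)
  ann <- eventAnnotations(sp)
  expect_gt(nrow(ann), 0)
  fs <- samplingRate(sp)
  thresh <- stats::quantile(abs(signalData(s)), 0.999)
  peaks <- vapply(seq_len(nrow(ann)), function(k) {
    ch <- ann$channel[k]
    i0 <- round(ann$time[k] * fs) + 1
    idx <- i0:min(ncol(signalData(sp)), i0 + round(0.07 * fs))
    max(abs(signalData(sp)[ch, idx]))
  }, numeric(1))
  expect_true(all(peaks > thresh))
  # shape invariants: duration and channel count unchanged
  expect_identical(dim(signalData(sp)), dim(signalData(s)))
  expect_error(injectSpikes(s, -1, 6), "spikeRate")
})

test_that("cohort generation respects group sizes and seeds", {
  spec <- cohortSpec(list(groupSpec("IED", 2L, spikeRate = 5),
                          groupSpec("nonIED", 0L),
                          groupSpec("HC", 3L)),
                     samplingRate = 1000, duration = 2, nChannels = 4L,
                     seed = 2L)
  ch <- generateCohort(spec)
  expect_length(ch$subjects, 5L)
  expect_identical(sum(grepl("^nonIED", names(ch$subjects))), 0L)
  grp <- vapply(ch$subjects, groupLabel, character(1))
  expect_identical(as.integer(table(grp)[c("HC", "IED")]), c(3L, 2L))
  # IED subjects carry spike annotations, HC none
  expect_true(all(vapply(ch$subjects[grp == "HC"], function(s)
    is.null(eventAnnotations(s)) || nrow(eventAnnotations(s)) == 0,
    logical(1))))
})

test_that("simulated scores follow the group distributions", {
  set.seed(1)
  ids <- sprintf("s%02d", 1:90)
  grp <- rep(c("IED", "nonIED", "HC"), each = 30)
  sc <- suppressWarnings(simulateScores(ids, grp, seed = 4))
  expect_identical(names(sc), c("subject_id", "group", "FSIQ", "VCI",
                                "PRI", "WMI", "PSI"))
  m <- tapply(sc$VCI, sc$group, mean)
  expect_lt(m[["IED"]], m[["HC"]])    # planted VCI deficit
  expect_error(simulateScores(ids, rep("??", 90)), "no score distribution")
})
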