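test_that("pairwise correlation matches the definitional formula", {
  # copy and negation
  x <- matrix(rnorm(300), 1)
  s <- SignalSet(rbind(x, x, -x), 100)
  R <- connMatrix(pairwiseCorrelation(s))
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)

  # hand-evaluated oracle: covariance over the product of SDs
  a <- c(1, 2, 3, 4)
  b <- c(1, 2, 3, 5)
  oracle <- sum((a - mean(a)) * (b - mean(b))) / (length(a) - 1) /
    (sd(a) * sd(b))
  R2 <- connMatrix(pairwiseCorrelation(SignalSet(rbind(a, b), 10)))
  expect_equal(R2[1, 2], oracle, tolerance = 1e-12)
  expect_identical(sampleCount(pairwiseCorrelation(SignalSet(rbind(a, b),
                                                             10))), 4L)
})

test_that("constant channels are excluded, not zeroed", {
  s <- SignalSet(rbind(rnorm(100), rep(1, 100), rnorm(100)), 100)
  expect_warning(conn <- pairwiseCorrelation(s), "constant")
  R <- connMatrix(conn)
  expect_true(all(is.na(R[2, ])))
  net <- buildNetwork(conn, alpha = 0.5)
  expect_true(all(edgeWeights(net)[2, ] == 0))
})

test_that("the correlation t statistic and its inversion agree", {
  # direct evaluation: R = 0.5, K = 27 -> Tp = 0.5 * 5 / sqrt(0.75)
  expect_equal(correlationT(0.5, 27), 2.8868, tolerance = 1e-4)
  expect_equal(correlationT(0, 100), 0)
  # monotonicity in K
  expect_lt(criticalR(30000), criticalR(300))
  # round trip: Tp at the critical R equals the t quantile
  for (K in c(10L, 100L, 5000L)) {
    for (alpha in c(0.01, 0.05, 0.2)) {
      rc <- criticalR(K, alpha)
      expect_equal(correlationT(rc, K), qt(1 - alpha / 2, K - 2),
                   tolerance = 1e-10)
    }
  }
  expect_error(criticalR(2), "K must be")
  expect_error(criticalR(10, 1.5), "alpha")
})

test_that("thresholding equals a per-pair t-test and nests in alpha", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 6
    K <- 40
    x <- matrix(rnorm(n * K), n)
    x[2, ] <- x[2, ] + 0.8 * x[1, ]      # a few real edges
    s <- SignalSet(x, 100)
    conn <- pairwiseCorrelation(s)
    prev <- NULL
    for (alpha in c(0.01, 0.05, 0.1)) {
      net <- buildNetwork(conn, alpha)
      w <- edgeWeights(net)
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        pOracle <- cor.test(x[i, ], x[j, ])$p.value
        expect_identical(w[i, j] != 0, pOracle < alpha)
        if (w[i, j] != 0)
          expect_identical(w[i, j], connMatrix(conn)[i, j])  # sign kept
      }
      if (!is.null(prev))   # smaller alpha -> subset of edges
        expect_true(all(which(prev != 0) %in% which(w != 0)))
      prev <- w
    }
  }
})

test_that("a 0.5 threshold keeps exactly the two strong signed edges", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.9
  R[1, 3] <- R[3, 1] <- 0.1
  R[2, 3] <- R[3, 2] <- -0.9
  K <- 18L
  conn <- new("ConnectivityResult", R = R, K = K,
              band = defaultBands()[0, ], subjectId = "toy",
              group = "none", excluded = integer(0))
  alpha <- 2 * (1 - pt(correlationT(0.5, K), K - 2))  # threshold_R = 0.5
  net <- buildNetwork(conn, alpha)
  w <- edgeWeights(net)
  expect_equal(net@thresholdR, 0.5, tolerance = 1e-12)
  expect_identical(sum(w[upper.tri(w)] != 0), 2L)
  expect_equal(w[1, 2], 0.9)
  expect_equal(w[2, 3], -0.9)
  expect_equal(w[1, 3], 0)
})

test_that("regional edge counts partition the total", {
  meta <- data.frame(label = letters[1:4],
                     region = c("anterior", "anterior", "posterior",
                                "posterior"),
                     hemisphere = c("L", "R", "L", "R"))
  w <- matrix(0.8, 4, 4)
  diag(w) <- 0
  net <- new("ThresholdedNetwork", weights = w, thresholdR = 0.5,
             alpha = 0.05, K = 100L, band = defaultBands()[0, ],
             subjectId = "toy", group = "none")
  counts <- regionalEdgeCount(net, meta)
  expect_equal(unname(counts), c(1, 4, 1))
  # empty network
  net0 <- initialize(net, weights = matrix(0, 4, 4))
  expect_equal(unname(regionalEdgeCount(net0, meta)), c(0, 0, 0))
  # partition property on a random network
  set.seed(8)
  w2 <- randomWeightedGraph(4, 0.6)
  w2[w2 != 0] <- pmax(w2[w2 != 0], 0.5)
  net2 <- initialize(net, weights = w2)
  expect_equal(sum(regionalEdgeCount(net2, meta)),
               sum(w2[upper.tri(w2)] != 0))
  expect_error(regionalEdgeCount(net, meta[, 1:2][, c("label"), drop = FALSE]),
               "region")
})
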