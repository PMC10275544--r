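test_that("closed forms hold exactly on complete unit-weight graphs", {
  for (N in 3:8) {
    w <- matrix(1, N, N)
    diag(w) <- 0
    gm <- computeGraphMetrics(w)
    m <- networkMetrics(gm)
    expect_identical(unname(m["DA"]), N - 1)
    expect_equal(unname(m["SA"]), (N - 1) / N, tolerance = 1e-14)
    expect_equal(unname(m["LA"]), 1, tolerance = 1e-14)
    expect_equal(unname(m["CA"]), 1, tolerance = 1e-14)
  }
})

test_that("small worked examples match hand computation", {
  # path graph 1-2-3
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  d <- nodeDegree(w)
  expect_equal(d$d, c(1, 2, 1))
  expect_equal(d$DA, 4 / 3)

  # strength with the 1/N prefactor, and the conventional sum
  w4 <- matrix(1, 4, 4)
  diag(w4) <- 0
  expect_equal(nodeStrength(w4)$S, rep(0.75, 4))
  expect_equal(nodeStrength(w4, convention = "sum")$S, rep(3, 4))

  # triangle with a weak direct edge: detour is shorter
  wt <- matrix(0, 3, 3)
  wt[1, 2] <- wt[2, 1] <- 1
  wt[2, 3] <- wt[3, 2] <- 1
  wt[1, 3] <- wt[3, 1] <- 0.25
  pl <- pathLength(wt)
  expect_equal(pl$L[1, 3], 2)          # via node 2, not the 1/0.25 = 4 edge
  expect_equal(pl$L, fwPathOracle(wt), tolerance = 1e-12)

  # two disconnected nodes: unreachable contributes 0
  expect_equal(pathLength(matrix(0, 2, 2))$LA, 0)

  # unit triangle plus a pendant node
  wp <- matrix(0, 4, 4)
  wp[1, 2] <- wp[2, 1] <- 1
  wp[2, 3] <- wp[3, 2] <- 1
  wp[1, 3] <- wp[3, 1] <- 1
  wp[3, 4] <- wp[4, 3] <- 1
  cl <- clusteringCoefficient(wp)
  expect_equal(cl$C, c(1, 1, 1 / 3, 0))
  expect_equal(cl$CA, mean(c(1, 1, 1 / 3, 0)))
  # star graph: no triangles anywhere
  ws <- matrix(0, 5, 5)
  ws[1, -1] <- ws[-1, 1] <- 1
  expect_equal(clusteringCoefficient(ws)$CA, 0)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (k in 1:60) {
    n <- sample(3:8, 1)
    w <- randomWeightedGraph(n, runif(1, 0.2, 0.9))
    gm <- suppressWarnings(computeGraphMetrics(w))  # sparse draws may be empty
    expect_equal(nodeMetrics(gm)$degree, degreeOracle(w), tolerance = 1e-10)
    expect_equal(nodeMetrics(gm)$strength, strengthOracle(w),
                 tolerance = 1e-10)
    expect_equal(pathLengthMatrix(gm), fwPathOracle(w), tolerance = 1e-10)
    expect_equal(nodeMetrics(gm)$clustering, clusteringOracle(w),
                 tolerance = 1e-10)
  }
})

test_that("metrics scale as expected under weight rescaling", {
  set.seed(12)
  w <- randomWeightedGraph(6, 0.6)
  c0 <- computeGraphMetrics(w)
  c2 <- computeGraphMetrics(2.5 * w)
  expect_equal(nodeMetrics(c2)$degree, nodeMetrics(c0)$degree)
  expect_equal(nodeMetrics(c2)$strength, 2.5 * nodeMetrics(c0)$strength)
  expect_equal(pathLengthMatrix(c2), pathLengthMatrix(c0) / 2.5,
               tolerance = 1e-12)
  expect_equal(nodeMetrics(c2)$clustering, nodeMetrics(c0)$clustering,
               tolerance = 1e-12)
})

test_that("network-level metrics are permutation invariant", {
  set.seed(13)
  w <- randomWeightedGraph(7, 0.5)
  p <- sample(7)
  m1 <- networkMetrics(computeGraphMetrics(w))
  m2 <- networkMetrics(computeGraphMetrics(w[p, p]))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("degenerate networks are handled", {
  expect_warning(gm <- computeGraphMetrics(matrix(0, 4, 4)), "empty")
  expect_equal(unname(networkMetrics(gm)), c(0, 0, 0, 0))
  # an isolated node dilutes the averages
  set.seed(14)
  w <- randomWeightedGraph(5, 0.9)
  w2 <- rbind(cbind(w, 0), 0)
  m1 <- networkMetrics(computeGraphMetrics(w))
  m2 <- networkMetrics(computeGraphMetrics(w2))
  expect_lt(m2["DA"], m1["DA"])
  expect_lt(m2["SA"], m1["SA"])
  expect_lt(m2["CA"], m1["CA"])
})
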