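test_that("the normality gate picks the right omnibus test", {
  set.seed(41)
  # Gaussian, equal variance: ANOVA in about 0.95^3 * 0.95 = 81% of reps
  # (three per-group Shapiro gates plus the homogeneity gate, each at 0.05)
  picks <- replicate(200, chooseTest(list(rnorm(15), rnorm(15), rnorm(15))))
  expect_gte(mean(picks == "anova"), 0.70)
  expect_lte(mean(picks == "anova"), 0.92)
  # one heavy-tailed group: rank test in the majority of reps
  picks2 <- replicate(100, chooseTest(list(rnorm(15), rnorm(15),
                                           rcauchy(15))))
  expect_gt(mean(picks2 == "kruskal"), 0.5)
  # degenerate constant group
  expect_warning(t3 <- chooseTest(list(rep(1, 5), rep(1, 5))),
                 "zero-variance")
  expect_identical(as.vector(t3), "kruskal")
  expect_error(chooseTest(list(rnorm(2), rnorm(15))), ">= 3 values")
})

test_that("Bonferroni bookkeeping matches the three-group convention", {
  set.seed(42)
  res <- compareGroups(rnorm(45), rep(c("A", "B", "C"), each = 15))
  expect_identical(res$alphaCorrected, 0.05 / 3)
  # printed to the reference precision: p < .016
  expect_identical(substr(sprintf("%.4f", res$alphaCorrected), 1, 5),
                   "0.016")
  expect_identical(res$alphaCorrected * nrow(res$pairwise), 0.05)
  expect_true(all(res$pairwise$pCorrected >= res$pairwise$p))
})

test_that("identical groups give p = 1 under the rank test", {
  v <- rexp(15)   # non-normal so the gate picks Kruskal-Wallis
  res <- compareGroups(c(v, v), rep(c("A", "B"), each = 15))
  expect_identical(res$testUsed, "kruskal")
  expect_equal(res$pairwise$p, 1, tolerance = 1e-12)
})

test_that("a planted group effect is detected with high power", {
  set.seed(43)
  hits <- replicate(100, {
    vals <- c(rnorm(15), rnorm(15), rnorm(15, mean = 1.5))  # d = 1.5
    res <- compareGroups(vals, rep(c("A", "B", "C"), each = 15))
    pw <- res$pairwise
    any(pw$significant[pw$groupA == "A" & pw$groupB == "C" |
                         pw$groupA == "C" & pw$groupB == "A"])
  })
  expect_gte(mean(hits), 0.8)
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(44)
  vals <- c(rexp(12), rexp(12, 0.5))
  grp <- rep(c("A", "B"), each = 12)
  p1 <- kruskal.test(vals, factor(grp))$p.value
  p2 <- kruskal.test(exp(vals), factor(grp))$p.value
  expect_equal(p1, p2, tolerance = 1e-12)
  # and through the package interface
  r1 <- compareGroups(vals, grp)
  r2 <- compareGroups(exp(vals), grp)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
})

test_that("correlation picks its method from the normality of both sides", {
  x <- 1:12
  y <- 2 * x + 1
  expect_equal(correlateWithScore(x, y, "pearson")$estimate, 1)
  expect_equal(correlateWithScore(x, y, "spearman")$estimate, 1)
  # monotone nonlinear with a heavy tail: Spearman, perfect rank agreement
  set.seed(45)
  xh <- rcauchy(20)
  r <- correlateWithScore(xh, xh^3)
  expect_identical(r$method, "spearman")
  expect_equal(r$estimate, 1)
  expect_error(correlateWithScore(1:3, 1:4), "mismatch")
  expect_error(correlateWithScore(1:4, 1:4), "at least 5")
})

test_that("null correlations stay below the critical value at ~95%", {
  set.seed(46)
  n <- 15
  crit <- criticalR(n, 0.05)
  inside <- replicate(200, {
    x <- rnorm(n)
    y <- sample(x)
    abs(correlateWithScore(x, y, "pearson")$estimate) <= crit
  })
  expect_gte(mean(inside), 0.90)
  expect_lte(mean(inside), 0.99)
})

test_that("the variance homogeneity test flags unequal spread", {
  set.seed(47)
  hom <- varianceHomogeneity(list(rnorm(30), rnorm(30)))
  het <- varianceHomogeneity(list(rnorm(30), rnorm(30, sd = 5)))
  expect_gt(hom$p.value, 0.05)
  expect_lt(het$p.value, 0.01)
})
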