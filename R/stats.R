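# Group comparison and metric-score correlation with the normality-gated
# test choice: Shapiro-Wilk per group plus a median-centred Levene
# homogeneity test decide between one-way ANOVA and Kruskal-Wallis;
# pairwise follow-ups are Bonferroni-corrected over the number of group
# pairs (three groups -> alpha/3, printed as p < .016).

#' Median-centred Levene test of variance homogeneity
#'
#' One-way ANOVA on the absolute deviations from each group's median
#' (the Brown-Forsythe form, robust to non-normality).
#'
#' @param samples list of numeric vectors, one per group.
#' @return list with `statistic`, `p.value`, `df`.
#' @export
varianceHomogeneity <- function(samples) {
  z <- unlist(lapply(samples, function(x) abs(x - stats::median(x))))
  g <- factor(rep(seq_along(samples), lengths(samples)))
  if (stats::var(z) == 0)
    return(list(statistic = 0, p.value = 1, df = c(length(samples) - 1L,
                                                   length(z) - length(samples))))
  fit <- stats::oneway.test(z ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p.value = fit$p.value,
       df = unname(fit$parameter))
}

#' Choose between ANOVA and Kruskal-Wallis
#'
#' Returns `"anova"` only when every group passes the Shapiro-Wilk
#' normality test at `alphaGate` *and* the variance-homogeneity test
#' passes at `alphaGate`; otherwise `"kruskal"`. Degenerate zero-variance
#' groups cannot be tested for normality and fall back to the rank test
#' with a warning.
#'
#' @param samples list of numeric vectors, one per group (each n >= 3).
#' @param alphaGate gate level for both checks (default 0.05).
#' @return `"anova"` or `"kruskal"` with attribute `"gates"` recording the
#'   per-group normality p-values and the homogeneity p-value.
#' @export
chooseTest <- function(samples, alphaGate = 0.05) {
  if (length(samples) < 2L) stop("need at least 2 groups")
  if (any(lengths(samples) < 3L)) stop("every group needs >= 3 values")
  if (any(vapply(samples, function(x) stats::var(x) == 0, logical(1)))) {
    warning("zero-variance group: falling back to the rank test")
    out <- "kruskal"
    attr(out, "gates") <- list(shapiro = rep(NA_real_, length(samples)),
                               homogeneity = NA_real_)
    return(out)
  }
  swp <- vapply(samples, function(x) stats::shapiro.test(x)$p.value,
                numeric(1))
  hom <- varianceHomogeneity(samples)$p.value
  out <- if (all(swp >= alphaGate) && hom >= alphaGate) "anova" else "kruskal"
  attr(out, "gates") <- list(shapiro = swp, homogeneity = hom)
  out
}

#' Omnibus and pairwise group comparison of one metric
#'
#' Runs the gated omnibus test ([chooseTest()]) and all pairwise two-group
#' tests (Student t after ANOVA, Mann-Whitney after Kruskal-Wallis), with
#' Bonferroni correction over the number of pairs: the family threshold is
#' `alpha / nPairs` and corrected p-values are `min(1, p * nPairs)`.
#'
#' @param values numeric vector of the metric (one value per subject).
#' @param groups group label per subject.
#' @param alpha family-wise significance level (default 0.05).
#' @param alphaGate gate level for the normality/homogeneity checks.
#' @param metric,band optional labels carried into the result.
#' @return a `GroupTestResult` list: `testUsed`, `statistic`, `p` (omnibus),
#'   `pairwise` (data.frame with `groupA`, `groupB`, `p`, `pCorrected`,
#'   `significant`), `alphaCorrected`, `gates`.
#' @examples
#' compareGroups(c(rnorm(15), rnorm(15), rnorm(15, 2)),
#'               rep(c("A", "B", "C"), each = 15))
#' @export
compareGroups <- function(values, groups, alpha = 0.05, alphaGate = 0.05,
                          metric = NA_character_, band = NA_character_) {
  if (length(values) != length(groups)) stop("length mismatch")
  groups <- as.character(groups)
  samples <- split(values, groups)
  test <- chooseTest(samples, alphaGate)
  g <- factor(groups)
  if (test == "anova") {
    fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
    stat <- unname(fit$statistic)
    pOmni <- fit$p.value
  } else {
    fit <- stats::kruskal.test(values, g)
    stat <- unname(fit$statistic)
    pOmni <- fit$p.value
  }
  nms <- names(samples)
  pairs <- utils::combn(nms, 2)
  nPairs <- ncol(pairs)
  pw <- data.frame(groupA = pairs[1, ], groupB = pairs[2, ],
                   p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nPairs)) {
    a <- samples[[pairs[1, k]]]
    b <- samples[[pairs[2, k]]]
    pw$p[k] <- if (test == "anova") {
      stats::t.test(a, b, var.equal = TRUE)$p.value
    } else if (all(c(a, b) == c(a, b)[1])) {
      1   # every value tied: no evidence either way
    } else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                          correct = FALSE)$p.value)
    }
  }
  pw$pCorrected <- pmin(1, pw$p * nPairs)
  alphaCorrected <- alpha / nPairs
  pw$significant <- pw$p < alphaCorrected
  structure(
    list(metric = metric, band = band, testUsed = as.vector(test),
         statistic = stat, p = pOmni, pairwise = pw,
         alpha = alpha, alphaCorrected = alphaCorrected,
         gates = attr(test, "gates")),
    class = "GroupTestResult")
}

#' @export
print.GroupTestResult <- function(x, ...) {
  lbl <- if (!is.na(x$metric)) sprintf(" [%s, %s]", x$metric, x$band) else ""
  cat(sprintf("Group comparison%s: %s, statistic = %.3f, p = %.4g\n",
              lbl, ifelse(x$testUsed == "anova", "one-way ANOVA",
                          "Kruskal-Wallis"), x$statistic, x$p))
  cat(sprintf("Pairwise threshold (Bonferroni over %d pairs): p < %.3f\n",
              nrow(x$pairwise), x$alphaCorrected))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Correlate a metric with a cognitive score
#'
#' Pearson when both variables pass Shapiro-Wilk normality at 0.05,
#' Spearman otherwise (`method = "auto"`); either can be forced.
#'
#' @param x,y paired numeric vectors (n >= 5).
#' @param method `"auto"` (default), `"pearson"` or `"spearman"`.
#' @return list with `estimate` (in [-1, 1]), `p.value` (two-sided) and
#'   `method` used.
#' @export
correlateWithScore <- function(x, y, method = c("auto", "pearson",
                                                "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 5L) stop("need at least 5 paired values")
  if (method == "auto") {
    norm <- function(v) stats::var(v) > 0 &&
      stats::shapiro.test(v)$p.value >= 0.05
    method <- if (norm(x) && norm(y)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       method = method)
}
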