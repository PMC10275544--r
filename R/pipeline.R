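# End-to-end orchestration: simulate (or load) -> notch -> band
# decomposition -> correlation -> threshold -> graph metrics -> group
# statistics and score correlations, all deterministic under one seed.

#' Build a pipeline configuration
#'
#' Either constructs the configuration from arguments or reads it from a
#' JSON file (`jsonPath`). Defaults mirror the reference analysis: a
#' three-group cohort of 15 subjects each, 30 channels, one 30-s window
#' at 1000 Hz, six bands, notch at 50 Hz, edge alpha 0.05 and family
#' alpha 0.05.
#'
#' @param cohort a [CohortSpec-class] (or `NULL` to analyse `inputDir`).
#' @param inputDir directory of [writeSignalSet()] pairs to analyse
#'   instead of simulating.
#' @param bands band table.
#' @param notchFreq mains frequency to notch out (Hz); `NA` disables.
#' @param alphaFc per-edge significance level.
#' @param alphaStats family-wise level for group comparisons.
#' @param scores `"simulate"`, a CSV path, or `NA` to skip correlations.
#' @param outDir output directory (`NA` = return tables only).
#' @param seed master seed (required with a cohort spec).
#' @param jsonPath read the configuration from this JSON file instead;
#'   fields mirror the argument names, `cohort` reduced to
#'   `nSubjects`/`nChannels`/`samplingRate`/`duration`.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(cohort = NULL, inputDir = NA_character_,
                           bands = defaultBands(), notchFreq = 50,
                           alphaFc = 0.05, alphaStats = 0.05,
                           scores = "simulate", outDir = NA_character_,
                           seed = 1L, jsonPath = NULL) {
  if (!is.null(jsonPath)) {
    js <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
    bad <- setdiff(names(js), c("nSubjects", "nChannels", "samplingRate",
                                "duration", "notchFreq", "alphaFc",
                                "alphaStats", "scores", "outDir", "seed",
                                "inputDir"))
    if (length(bad))
      stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")))
    get <- function(nm, dflt) if (!is.null(js[[nm]])) js[[nm]] else dflt
    seed <- get("seed", seed)
    cohort <- if (is.null(js$inputDir))
      defaultCohortSpec(nSubjects = get("nSubjects", 15L),
                        nChannels = get("nChannels", 30L),
                        samplingRate = get("samplingRate", 1000),
                        duration = get("duration", 30),
                        seed = seed)
    else NULL
    inputDir <- get("inputDir", NA_character_)
    notchFreq <- get("notchFreq", notchFreq)
    alphaFc <- get("alphaFc", alphaFc)
    alphaStats <- get("alphaStats", alphaStats)
    scores <- get("scores", scores)
    outDir <- get("outDir", outDir)
  }
  if (is.null(cohort) && is.na(inputDir))
    stop("config needs either a cohort spec or an inputDir")
  if (!is.null(cohort) && is.na(seed))
    stop("a seed is required when simulating a cohort")
  structure(list(cohort = cohort, inputDir = inputDir, bands = bands,
                 notchFreq = notchFreq, alphaFc = alphaFc,
                 alphaStats = alphaStats, scores = scores,
                 outDir = outDir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Validate analysis inputs
#'
#' Non-mutating checks: matrix shape vs metadata, finite values,
#' sampling-rate adequacy for each requested band. Problems are reported,
#' not thrown.
#'
#' @param subjects list of [SignalSet-class] objects (or a single one).
#' @param bands band table the analysis will request.
#' @return data.frame with columns `subject`, `problem` (0 rows when all
#'   inputs are well-formed).
#' @export
validateInputs <- function(subjects, bands = defaultBands()) {
  if (methods::is(subjects, "SignalSet")) subjects <- list(subjects)
  problems <- data.frame(subject = character(0), problem = character(0),
                         stringsAsFactors = FALSE)
  note <- function(sid, msg)
    rbind(problems, data.frame(subject = sid, problem = msg,
                               stringsAsFactors = FALSE))
  for (s in subjects) {
    sid <- tryCatch(subjectId(s), error = function(e) "?")
    x <- s@data
    if (nrow(s@channels) != nrow(x))
      problems <- note(sid, sprintf(
        "metadata channel count (%d) != matrix rows (%d)",
        nrow(s@channels), nrow(x)))
    if (any(!is.finite(x)))
      problems <- note(sid, "non-finite values in data")
    for (i in seq_len(nrow(bands)))
      if (bands$high[i] >= s@samplingRate / 2)
        problems <- note(sid, sprintf(
          "band '%s' top edge %g Hz at or above Nyquist (%g Hz)",
          bands$name[i], bands$high[i], s@samplingRate / 2))
  }
  problems
}

.loadInputDir <- function(dir) {
  metas <- list.files(dir, pattern = "_meta\\.json$", full.names = TRUE)
  if (!length(metas)) stop(sprintf("no signal sets found in %s", dir))
  prefixes <- sub("_meta\\.json$", "", metas)
  subjects <- lapply(prefixes, readSignalSet)
  names(subjects) <- vapply(subjects, subjectId, character(1))
  subjects
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the cohort, then per subject: notch filter, band
#' decomposition, pairwise correlation, t-threshold network, graph
#' metrics and regional edge counts; finally group comparisons for each
#' band x metric and per-group metric-score correlations. Deterministic
#' given the seed. When `outDir` is set, all tables are written as CSV
#' along with a JSON manifest sufficient to re-run bit-identically.
#'
#' @param config a [pipelineConfig()].
#' @return a `RunReport` list with `metricsTable` (one row per subject x
#'   band: DA/SA/LA/CA and edge counts by region pair), `groupTests`
#'   (band x metric omnibus + pairwise results), `correlations`
#'   (per group x band x metric x score), `scores`, `groundTruth`,
#'   `manifest`.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(cohort = defaultCohortSpec(nSubjects = 2,
#'   nChannels = 6, duration = 4, samplingRate = 1000, seed = 1))
#' rep <- runPipeline(cfg)
#' head(rep$metricsTable)
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(config$cohort)) {
    cohort <- generateCohort(config$cohort)
    subjects <- cohort$subjects
    groundTruth <- cohort$groundTruth
  } else {
    subjects <- .loadInputDir(config$inputDir)
    groundTruth <- NULL
  }
  probs <- validateInputs(subjects, config$bands)
  if (nrow(probs))
    stop(sprintf("invalid input for subject %s: %s",
                 probs$subject[1], probs$problem[1]))

  bands <- config$bands
  rows <- list()
  for (sid in names(subjects)) {
    s <- subjects[[sid]]
    ok <- tryCatch({
      if (!is.na(config$notchFreq))
        s <- notchFilter(s, config$notchFreq)
      for (i in seq_len(nrow(bands))) {
        band <- bands[i, ]
        filt <- bandpassFilter(s, band)
        conn <- pairwiseCorrelation(filt, band = band)
        net <- buildNetwork(conn, alpha = config$alphaFc)
        gm <- computeGraphMetrics(net)
        counts <- regionalEdgeCount(net, channelInfo(s))
        m <- networkMetrics(gm)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = groupLabel(s), band = band$name,
          DA = m[["DA"]], SA = m[["SA"]], LA = m[["LA"]], CA = m[["CA"]],
          edges_total = sum(counts),
          edges_anterior_anterior = counts[["anterior_anterior"]],
          edges_anterior_posterior = counts[["anterior_posterior"]],
          edges_posterior_posterior = counts[["posterior_posterior"]],
          stringsAsFactors = FALSE)
      }
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop(sprintf("pipeline failed for subject %s: %s", sid,
                   conditionMessage(ok)))
  }
  metricsTable <- do.call(rbind, rows)
  rownames(metricsTable) <- NULL

  groupTests <- NULL
  grpSizes <- table(metricsTable$subject_id, metricsTable$group)
  nPerGroup <- colSums(grpSizes > 0)
  if (length(nPerGroup) >= 2 && all(nPerGroup >= 3)) {
    gt <- list()
    for (b in bands$name) {
      sub <- metricsTable[metricsTable$band == b, ]
      for (metric in c("DA", "SA", "LA", "CA")) {
        res <- compareGroups(sub[[metric]], sub$group,
                             alpha = config$alphaStats,
                             metric = metric, band = b)
        pw <- res$pairwise
        gt[[length(gt) + 1L]] <- data.frame(
          band = b, metric = metric, test = res$testUsed,
          statistic = res$statistic, p_omnibus = res$p,
          comparison = paste(pw$groupA, pw$groupB, sep = "_vs_"),
          p_pairwise = pw$p, p_corrected = pw$pCorrected,
          alpha_corrected = res$alphaCorrected,
          significant = pw$significant,
          stringsAsFactors = FALSE)
      }
    }
    groupTests <- do.call(rbind, gt)
    rownames(groupTests) <- NULL
  }

  scores <- NULL
  correlations <- NULL
  if (!is.na(config$scores)) {
    scores <- if (identical(config$scores, "simulate")) {
      simulateScores(subjects, seed = .deriveSeed(config$seed, 999983L))
    } else readScores(config$scores)
    scoreCols <- intersect(c("FSIQ", "VCI", "PRI", "WMI", "PSI"),
                           names(scores))
    cr <- list()
    for (g in unique(metricsTable$group)) {
      for (b in bands$name) {
        sub <- metricsTable[metricsTable$group == g &
                              metricsTable$band == b, ]
        sc <- scores[match(sub$subject_id, scores$subject_id), ]
        if (nrow(sub) < 5L || any(is.na(sc$subject_id))) next
        for (metric in c("DA", "SA", "LA", "CA")) {
          for (scn in scoreCols) {
            r <- correlateWithScore(sub[[metric]], sc[[scn]])
            cr[[length(cr) + 1L]] <- data.frame(
              group = g, band = b, metric = metric, score = scn,
              R = r$estimate, p = r$p.value, method = r$method,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(cr)) {
      correlations <- do.call(rbind, cr)
      rownames(correlations) <- NULL
    }
  }

  manifest <- list(
    seed = config$seed,
    alphaFc = config$alphaFc,
    alphaStats = config$alphaStats,
    notchFreq = config$notchFreq,
    bands = bands,
    nSubjects = length(subjects),
    package = "megconn",
    version = as.character(utils::packageVersion("megconn")))

  report <- structure(list(metricsTable = metricsTable,
                           groupTests = groupTests,
                           correlations = correlations,
                           scores = scores,
                           groundTruth = groundTruth,
                           manifest = manifest),
                      class = "RunReport")
  if (!is.na(config$outDir)) writeRunReport(report, config$outDir)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport: %d subjects x %d bands (%d metric rows)\n",
              length(unique(x$metricsTable$subject_id)),
              length(unique(x$metricsTable$band)),
              nrow(x$metricsTable)))
  if (!is.null(x$groupTests)) {
    sig <- x$groupTests[x$groupTests$significant, ]
    cat(sprintf("Group tests: %d comparisons, %d significant at p < %.3f\n",
                nrow(x$groupTests), nrow(sig),
                x$groupTests$alpha_corrected[1]))
    if (nrow(sig)) print(sig[, c("band", "metric", "comparison",
                                 "p_pairwise", "p_corrected")],
                         row.names = FALSE)
  }
  invisible(x)
}

#' Write a run report's tables and manifest
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeRunReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(df, nm) if (!is.null(df))
    utils::write.csv(df, file.path(outDir, nm), row.names = FALSE)
  out(report$metricsTable, "graph_metrics.csv")
  out(report$groupTests, "group_tests.csv")
  out(report$correlations, "correlations.csv")
  out(report$scores, "scores.csv")
  jsonlite::write_json(report$manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
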