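#' Paired half-dataset resampling significance test
#'
#' Compares two predictors on the same protein set by repeatedly
#' (default 10 times) drawing half the proteins without replacement,
#' computing the chosen metric for both predictors on each draw (the
#' same draw for both — a paired design), and testing the paired
#' differences: an Anderson-Darling normality check at 0.05 gates a
#' paired t-test (normal) versus a Wilcoxon signed-rank test
#' (non-normal); p-values are two-sided. All-zero differences (e.g. a
#' predictor compared with itself) are reported as p = 1 with a
#' `"degenerate_differences"` flag.
#'
#' Predictor outputs may be given as fixed per-protein tracks (a named
#' list parallel to `labels`) or as a function of the sampled protein
#' ids returning such tracks — the latter models a predictor that is
#' stochastic at evaluation time, which is what a calibration study of
#' the procedure under a random-predictor null requires (a frozen pair
#' of random assignments differs by a genuine dataset-level offset that
#' this test is designed to detect).
#'
#' @param labels named list of per-protein 0/1 tracks.
#' @param predA,predB per-protein tracks (propensities for `metric =
#'   "AUC"`, binary calls for `"F1"`/`"MCC"`), or `function(ids)`
#'   returning them.
#' @param metric `"AUC"`, `"F1"` or `"MCC"`.
#' @param nReps number of half-dataset replicates (default 10).
#' @param seed integer seed for the replicate draws.
#' @return List with per-replicate metric values (`valuesA`, `valuesB`),
#'   `differences`, `adPValue`, `normal`, `test` (`"paired_t"`,
#'   `"wilcoxon"` or `"none"`), two-sided `pValue`, `nReps`, `seed`,
#'   `flags` and `redraws`.
#' @export
resamplingSignificance <- function(labels, predA, predB,
                                   metric = c("AUC", "F1", "MCC"),
                                   nReps = 10L, seed = 1L) {
  metric <- match.arg(metric)
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be a named list of tracks")
  n <- length(ids)
  if (n < 4L) stop("resampling needs at least 4 proteins")
  for (pred in list(predA, predB)) {
    if (!is.function(pred) && !all(ids %in% names(pred))) {
      stop("both predictors must cover every labelled protein")
    }
  }
  half <- n %/% 2L

  evalMetric <- function(y, tr) {
    if (metric == "AUC") {
      if (length(unique(y)) < 2L) return(NA_real_)
      fastAuc(tr, y)
    } else {
      bm <- binaryMetrics(y, tr)
      if (metric == "MCC" && "mcc_denominator_zero" %in% bm$flags) {
        return(NA_real_)
      }
      if (metric == "F1") bm$f1 else bm$mcc
    }
  }

  valuesA <- valuesB <- numeric(nReps)
  redraws <- 0L
  flags <- character(0)
  set.seed(seed)
  for (r in seq_len(nReps)) {
    repeat {
      sel <- sample(ids, half)
      y <- unlist(labels[sel], use.names = FALSE)
      ta <- if (is.function(predA)) predA(sel) else predA[sel]
      tb <- if (is.function(predB)) predB(sel) else predB[sel]
      a <- evalMetric(y, unlist(ta, use.names = FALSE))
      b <- evalMetric(y, unlist(tb, use.names = FALSE))
      if (is.na(a) || is.na(b)) {
        redraws <- redraws + 1L
        if (redraws > 100L) stop("metric undefined on repeated replicates")
        next
      }
      valuesA[r] <- a
      valuesB[r] <- b
      break
    }
  }
  if (redraws > 0L) flags <- c(flags, "replicates_redrawn")

  d <- valuesA - valuesB
  if (all(d == 0)) {
    return(list(
      metric = metric, valuesA = valuesA, valuesB = valuesB,
      differences = d, adPValue = NA_real_, normal = NA,
      test = "none", pValue = 1, nReps = nReps, seed = seed,
      flags = c(flags, "degenerate_differences"), redraws = redraws
    ))
  }
  if (stats::sd(d) == 0) {
    # constant non-zero differences: AD and t are undefined
    tst <- stats::wilcox.test(d, exact = FALSE)
    return(list(
      metric = metric, valuesA = valuesA, valuesB = valuesB,
      differences = d, adPValue = NA_real_, normal = NA,
      test = "wilcoxon", pValue = tst$p.value, nReps = nReps,
      seed = seed, flags = c(flags, "constant_differences"),
      redraws = redraws
    ))
  }
  adP <- nortest::ad.test(d)$p.value
  normal <- adP >= 0.05
  if (normal) {
    tst <- stats::t.test(valuesA, valuesB, paired = TRUE)
    testName <- "paired_t"
  } else {
    tst <- stats::wilcox.test(valuesA, valuesB, paired = TRUE, exact = FALSE)
    testName <- "wilcoxon"
  }
  list(
    metric = metric, valuesA = valuesA, valuesB = valuesB,
    differences = d, adPValue = adP, normal = normal,
    test = testName, pValue = tst$p.value, nReps = nReps, seed = seed,
    flags = flags, redraws = redraws
  )
}

#' Serialize a resampling report as JSON
#'
#' @param report list from [resamplingSignificance()].
#' @param path output file.
#' @export
writeResamplingReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
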