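#' Confusion counts and binary classification metrics
#'
#' Pools residues (or proteins) and computes TP/FP/TN/FN together with
#' MCC, F1, TPR and FPR under the standard definitions
#' `F1 = 2TP/(2TP+FP+FN)`,
#' `MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' `TPR = TP/(TP+FN)`, `FPR = FP/(FP+TN)`. A zero MCC denominator yields
#' MCC = 0 with a `"mcc_denominator_zero"` flag rather than NaN.
#'
#' @param labels 0/1 vector (or list of per-protein vectors, pooled).
#' @param predictions 0/1 vector or list, same shape as `labels`.
#' @return List with `counts` (named TP/FP/TN/FN), `mcc`, `f1`, `tpr`,
#'   `fpr`, `n` and `flags`.
#' @examples
#' binaryMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
binaryMetrics <- function(labels, predictions) {
  y <- as.integer(unlist(labels, use.names = FALSE))
  p <- as.integer(unlist(predictions, use.names = FALSE))
  if (length(y) != length(p)) {
    stop("labels and predictions differ in length (", length(y),
      " vs ", length(p), ")")
  }
  stopifnot(all(y %in% 0:1), all(p %in% 0:1))
  tp <- as.numeric(sum(y == 1L & p == 1L))
  fp <- as.numeric(sum(y == 0L & p == 1L))
  tn <- as.numeric(sum(y == 0L & p == 0L))
  fn <- as.numeric(sum(y == 1L & p == 0L))
  flags <- character(0)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den2 == 0) {
    mcc <- 0
    flags <- c(flags, "mcc_denominator_zero")
  } else {
    mcc <- (tp * tn - fp * fn) / sqrt(den2)
  }
  f1 <- if (2 * tp + fp + fn == 0) {
    flags <- c(flags, "f1_no_positives")
    0
  } else {
    2 * tp / (2 * tp + fp + fn)
  }
  list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    mcc = mcc,
    f1 = f1,
    tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    n = length(y),
    flags = flags
  )
}

#' ROC curve and AUC by the all-unique-thresholds construction
#'
#' The ROC is traced by thresholding the propensities at every unique
#' propensity value the predictor produced (predicting positive at or
#' above each threshold), plus the (0,0) endpoint; AUC is the trapezoidal
#' integral. Tied propensities are grouped at one threshold, which is
#' equivalent to giving half credit to tied positive-negative pairs in
#' the pair-ordering view of AUC.
#'
#' @param propensities numeric vector (or list, pooled over proteins).
#' @param labels 0/1 vector or list of the same shape.
#' @return List with `auc` and `roc` (matrix with columns fpr/tpr, from
#'   (0,0) to (1,1)).
#' @examples
#' rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc # 0.75
#' @export
rocAuc <- function(propensities, labels) {
  p <- as.numeric(unlist(propensities, use.names = FALSE))
  y <- as.integer(unlist(labels, use.names = FALSE))
  if (length(p) != length(y)) stop("propensities/labels length mismatch")
  nPos <- sum(y == 1L)
  nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L) {
    stop("ROC needs both classes present")
  }
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]
  ys <- y[ord]
  # group tied propensities at a single threshold
  newGrp <- c(TRUE, ps[-1L] != ps[-length(ps)])
  grp <- cumsum(newGrp)
  cumTp <- cumsum(ys == 1L)
  cumFp <- cumsum(ys == 0L)
  last <- which(c(newGrp[-1L], TRUE))
  roc <- cbind(
    fpr = c(0, cumFp[last] / nNeg),
    tpr = c(0, cumTp[last] / nPos)
  )
  auc <- sum(diff(roc[, "fpr"]) *
    (utils::head(roc[, "tpr"], -1L) + utils::tail(roc[, "tpr"], -1L)) / 2)
  list(auc = auc, roc = roc)
}

# rank-statistic AUC; same value as rocAuc (half credit for ties), used
# in training loops where the curve itself is not needed
fastAuc <- function(propensities, labels) {
  y <- as.integer(labels)
  nPos <- sum(y == 1L)
  nNeg <- length(y) - nPos
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(propensities)
  (sum(r[y == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Evaluate one predictor on one dataset
#'
#' Dataset-level (pooled-residue) assessment: ROC-AUC from propensities
#' plus MCC/F1/TPR/FPR from binary calls. `perProtein = TRUE` instead
#' averages per-protein metric values (non-default; proteins whose
#' labels are single-class are skipped for AUC).
#'
#' @param labels list of per-protein 0/1 tracks (or one vector).
#' @param propensities matching propensity tracks.
#' @param binaries matching binary tracks.
#' @param perProtein average per-protein metrics instead of pooling.
#' @return List with `auc`, `mcc`, `f1`, `tpr`, `fpr`, `counts`, `roc`,
#'   `n`, `flags`.
#' @export
evaluatePredictor <- function(labels, propensities, binaries,
                              perProtein = FALSE) {
  if (perProtein) {
    stopifnot(is.list(labels))
    per <- mapply(function(y, pr, b) {
      a <- if (length(unique(y)) == 2L) fastAuc(pr, y) else NA_real_
      bm <- binaryMetrics(y, b)
      c(auc = a, mcc = bm$mcc, f1 = bm$f1)
    }, labels, propensities, binaries)
    return(list(
      auc = mean(per["auc", ], na.rm = TRUE),
      mcc = mean(per["mcc", ]),
      f1 = mean(per["f1", ]),
      tpr = NA_real_, fpr = NA_real_, counts = NULL, roc = NULL,
      n = length(labels),
      flags = "per_protein_average"
    ))
  }
  r <- rocAuc(propensities, labels)
  b <- binaryMetrics(labels, binaries)
  list(
    auc = r$auc, mcc = b$mcc, f1 = b$f1, tpr = b$tpr, fpr = b$fpr,
    counts = b$counts, roc = r$roc, n = b$n, flags = b$flags
  )
}

#' Fully disordered protein calling
#'
#' A protein is fully disordered when its disordered residues cover at
#' least 95% of the chain; the same rule applied to predicted binary
#' calls gives the predicted status. The comparator is configurable
#' (`ge` for >=, `gt` for strict >) because published phrasings differ;
#' the default is >=.
#'
#' @param track per-residue 0/1 vector (truth labels, or predicted
#'   binary calls for `fullyDisorderedPrediction`).
#' @param cutoff disorder-coverage cutoff (default 0.95).
#' @param comparator `"ge"` (default) or `"gt"`.
#' @return Logical scalar.
#' @examples
#' fullyDisorderedTruth(c(rep(1, 19), 0)) # 19/20 = 0.95 -> TRUE
#' @export
fullyDisorderedTruth <- function(track, cutoff = 0.95, comparator = "ge") {
  stopifnot(length(track) >= 1L)
  frac <- mean(track == 1L)
  if (comparator == "ge") frac >= cutoff else frac > cutoff
}

#' @rdname fullyDisorderedTruth
#' @export
fullyDisorderedPrediction <- function(track, cutoff = 0.95,
                                      comparator = "ge") {
  fullyDisorderedTruth(track, cutoff, comparator)
}

#' Protein-level evaluation of fully-disordered calling
#'
#' @param truths logical vector, one per protein.
#' @param predictions logical vector, one per protein.
#' @return As [binaryMetrics()], computed over proteins. If the truth
#'   set is single-class the MCC is undefined: it is reported as `NA`
#'   with an `"mcc_undefined_single_class_truth"` flag and a warning,
#'   while F1 is still returned.
#' @export
evaluateFullyDisordered <- function(truths, predictions) {
  stopifnot(length(truths) == length(predictions))
  out <- binaryMetrics(as.integer(truths), as.integer(predictions))
  if (length(unique(as.integer(truths))) < 2L) {
    warning("single-class truth set: MCC undefined")
    out$mcc <- NA_real_
    out$flags <- c(out$flags, "mcc_undefined_single_class_truth")
  }
  out
}

#' Write a metrics report as JSON / ROC points as TSV
#'
#' @param report list from [evaluatePredictor()] or [binaryMetrics()].
#' @param path output file.
#' @export
writeMetricsReport <- function(report, path) {
  roc <- report$roc
  report$roc <- NULL
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(roc)) {
    utils::write.table(
      roc, sub("\\.json$", "_roc.tsv", path),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(path)
}
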