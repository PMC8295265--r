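test_that("binary metrics reproduce the defining formulas", {
  y <- c(1, 1, 0, 0, 1)
  perfect <- binaryMetrics(y, y)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)

  inverted <- binaryMetrics(y, 1 - y)
  expect_equal(inverted$mcc, -1)

  # TP=3 FP=1 FN=1 TN=5
  yy <- c(rep(1, 4), rep(0, 6))
  pp <- c(1, 1, 1, 0, 1, rep(0, 5))
  m <- binaryMetrics(yy, pp)
  expect_equal(unname(m$counts), c(3, 1, 5, 1))
  expect_equal(m$f1, 0.75)
  expect_equal(m$mcc, (3 * 5 - 1 * 1) / sqrt(4 * 4 * 6 * 6))
  expect_equal(m$tpr, 3 / 4)
  expect_equal(m$fpr, 1 / 6)
})

test_that("binary metrics are permutation invariant and MCC is symmetric", {
  set.seed(20)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.4)
    p <- rbinom(30, 1, 0.5)
    o <- sample(30)
    expect_equal(binaryMetrics(y, p), binaryMetrics(y[o], p[o]))
    expect_equal(binaryMetrics(y, p)$mcc, binaryMetrics(p, y)$mcc)
  }
})

test_that("zero MCC denominator yields 0 with a flag, not NaN", {
  m <- binaryMetrics(c(1, 1, 0), c(1, 1, 1))
  expect_equal(m$mcc, 0)
  expect_true("mcc_denominator_zero" %in% m$flags)
})

test_that("mismatched track lengths are an error", {
  expect_error(binaryMetrics(c(1, 0), c(1, 0, 1)), "length")
})

test_that("ROC construction anchors: perfect, random, worked example", {
  expect_equal(rocAuc(c(0, 1, 0, 1), c(0, 1, 0, 1))$auc, 1)
  expect_equal(rocAuc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(rocAuc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(rocAuc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("ROC curve is a valid monotone path from (0,0) to (1,1)", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 1) # force ties
    r <- rocAuc(p, y)$roc
    expect_equal(unname(r[1, ]), c(0, 0))
    expect_equal(unname(r[nrow(r), ]), c(1, 1))
    expect_true(all(diff(r[, "fpr"]) >= 0))
    expect_true(all(diff(r[, "tpr"]) >= 0))
  }
})

test_that("AUC equals the pair-ordering oracle, with half-credit ties", {
  set.seed(22)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(rocAuc(p, y)$auc, pairOrderAuc(p, y))
  }
  # reversed ranking complements the AUC
  y <- rbinom(30, 1, 0.4)
  y[1:2] <- c(0, 1)
  p <- runif(30)
  expect_equal(rocAuc(1 - p, y)$auc, 1 - rocAuc(p, y)$auc)
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(23)
  y <- c(0, 1, rbinom(200, 1, 0.3))
  p <- runif(202) + 0.4 * y
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
    direction = "<")))
  expect_equal(rocAuc(p, y)$auc, ref, tolerance = 1e-12)
})

test_that("fully disordered calling applies the 95% rule inclusively", {
  expect_true(fullyDisorderedTruth(rep(1, 20)))
  expect_true(fullyDisorderedTruth(c(rep(1, 19), 0))) # exactly 0.95
  expect_false(fullyDisorderedTruth(c(rep(1, 18), 0, 0))) # 0.90
  expect_false(fullyDisorderedTruth(c(rep(1, 19), 0), comparator = "gt"))
  expect_true(fullyDisorderedPrediction(1L)) # degenerate length-1 chain
})

test_that("protein-level fully-disordered evaluation matches hand counts", {
  truths <- c(TRUE, TRUE, FALSE, FALSE)
  preds <- c(TRUE, FALSE, FALSE, FALSE)
  m <- evaluateFullyDisordered(truths, preds)
  expect_equal(unname(m$counts), c(1, 0, 2, 1))
  expect_equal(m$f1, 2 / 3)

  ten <- rep(c(TRUE, FALSE), 5)
  expect_equal(evaluateFullyDisordered(ten, ten)$mcc, 1)

  expect_warning(
    m2 <- evaluateFullyDisordered(rep(TRUE, 4), c(TRUE, TRUE, FALSE, TRUE)),
    "single-class"
  )
  expect_true(is.na(m2$mcc))
  expect_equal(m2$f1, 2 * 3 / (2 * 3 + 0 + 1))
})

test_that("per-protein averaged variant is available and flagged", {
  labs <- list(a = c(1, 0, 1, 0), b = c(0, 0, 1, 1))
  props <- list(a = c(0.9, 0.1, 0.8, 0.2), b = c(0.1, 0.2, 0.9, 0.8))
  bins <- lapply(props, function(p) as.integer(p > 0.5))
  ev <- evaluatePredictor(labs, props, bins, perProtein = TRUE)
  expect_true("per_protein_average" %in% ev$flags)
  expect_equal(ev$auc, 1)
})

test_that("reports serialize to JSON with ROC points as TSV", {
  y <- c(0, 1, 0, 1, 1, 0)
  p <- c(0.1, 0.8, 0.4, 0.9, 0.6, 0.3)
  ev <- evaluatePredictor(y, p, as.integer(p > 0.5))
  d <- withr::local_tempdir()
  path <- file.path(d, "metrics.json")
  writeMetricsReport(ev, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$auc, ev$auc)
  roc <- utils::read.delim(file.path(d, "metrics_roc.tsv"))
  expect_equal(ncol(roc), 2L)
  expect_equal(nrow(roc), nrow(ev$roc))

  r <- resamplingSignificance(
    stats::setNames(replicate(6, c(0L, 1L, rbinom(10, 1, 0.4)),
      simplify = FALSE), paste0("p", 1:6)),
    function(ids) lapply(ids, function(i) runif(12)),
    function(ids) lapply(ids, function(i) runif(12)),
    metric = "AUC", seed = 2
  )
  rp <- file.path(d, "resampling.json")
  writeResamplingReport(r, rp)
  expect_equal(jsonlite::read_json(rp)$metric, "AUC")
})
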