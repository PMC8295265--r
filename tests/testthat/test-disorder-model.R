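test_that("threshold selection maximizes F1 over unique propensities", {
  # enumerating all four candidates: 0.35 (inclusive rule) scores 0.8
  th <- selectThreshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(as.numeric(th), 0.35)
  expect_equal(attr(th, "f1"), 0.8)

  # perfect separation: the candidate achieving F1 = 1
  th2 <- selectThreshold(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(attr(th2, "f1"), 1)

  # all propensities equal: single candidate, all-positive F1
  th3 <- selectThreshold(rep(0.4, 6), c(1, 0, 1, 0, 1, 1))
  expect_equal(as.numeric(th3), 0.4)
  expect_equal(attr(th3, "f1"), 2 * 4 / (2 * 4 + 2 + 0))

  expect_error(selectThreshold(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("binary calls use the strict greater-than rule", {
  expect_equal(binarize(c(0.2, 0.5, 0.9), 0.5), c(0L, 0L, 1L))
  expect_equal(binarize(c(0.2, 0.5, 0.9), 1), c(0L, 0L, 0L))
  expect_equal(binarize(c(0, 0.5, 0.9), 0), c(0L, 1L, 1L))
})

test_that("raising the threshold never adds predicted-disordered residues", {
  set.seed(40)
  p <- runif(200)
  counts <- sapply(seq(0, 1, 0.05), function(t) sum(binarize(p, t)))
  expect_true(all(diff(counts) <= 0))
})

test_that("the network learns a separable synthetic signal", {
  fit <- smallSeparableFit()
  sp <- fit$splits
  sc <- defaultSchema()
  teX <- encodeDataset(sp$test$profiles, disorderEncodingConfig(), sc)
  teY <- unlist(disorderTracks(sp$test)[names(sp$test$profiles)])
  prop <- predictPropensity(fit$model, teX)
  expect_true(all(prop >= 0 & prop <= 1))
  expect_gte(rocAuc(prop, teY)$auc, 0.95)
  expect_false(is.na(threshold(fit$model)))
})

test_that("the logistic twin reaches comparable quality on the same features", {
  fit <- smallSeparableFit()
  lr <- trainDisorderModel(
    fit$train$X, fit$train$y, fit$val$X, fit$val$y,
    quickDnn(), kind = "logistic"
  )
  sp <- fit$splits
  teX <- encodeDataset(sp$test$profiles, disorderEncodingConfig(),
    defaultSchema())
  teY <- unlist(disorderTracks(sp$test)[names(sp$test$profiles)])
  expect_gte(rocAuc(predictPropensity(lr, teX), teY)$auc, 0.95)
})

test_that("training is deterministic given the seed", {
  fit <- smallSeparableFit()
  cfg <- DnnConfig(seed = 99L, maxEpochs = 5L)
  m1 <- trainDisorderModel(fit$train$X, fit$train$y, fit$val$X, fit$val$y,
    cfg)
  m2 <- trainDisorderModel(fit$train$X, fit$train$y, fit$val$X, fit$val$y,
    cfg)
  expect_identical(
    predictPropensity(m1, fit$val$X),
    predictPropensity(m2, fit$val$X)
  )
  expect_identical(m1@threshold, m2@threshold)
})

test_that("prediction is pointwise and validates its inputs", {
  fit <- smallSeparableFit()
  X <- fit$val$X[1:10, , drop = FALSE]
  attr(X, "fingerprint") <- attr(fit$val$X, "fingerprint")
  p <- predictPropensity(fit$model, X)
  dup <- rbind(X, X[3, , drop = FALSE])
  attr(dup, "fingerprint") <- attr(X, "fingerprint")
  pd <- predictPropensity(fit$model, dup)
  expect_equal(pd[11], p[3])

  expect_error(
    predictPropensity(fit$model, X[, 1:100, drop = FALSE]),
    "dimension"
  )
  Xbad <- X
  attr(Xbad, "fingerprint") <- "other|schema"
  expect_error(predictPropensity(fit$model, Xbad), "fingerprint")
})

test_that("training rejects single-class labels and dim mismatches", {
  fit <- smallSeparableFit()
  X <- fit$train$X[1:50, ]
  expect_error(
    trainDisorderModel(X, rep(1L, 50), fit$val$X, fit$val$y, quickDnn()),
    "single class"
  )
  cfg <- DnnConfig(inputDim = 10L)
  expect_error(
    trainDisorderModel(fit$train$X, fit$train$y, fit$val$X, fit$val$y,
      cfg),
    "input_dim mismatch"
  )
})

test_that("grid search picks by validation AUC with stable tie-breaks", {
  fit <- smallSeparableFit()
  # limit rows to keep the grid cheap
  idx <- 1:600
  X <- fit$train$X[idx, ]
  y <- fit$train$y[idx]
  single <- list(DnnConfig(seed = 1L, maxEpochs = 3L))
  g1 <- gridSearchDnn(single, X, y, fit$val$X, fit$val$y)
  expect_identical(g1$config, single[[1]])

  # an undertrained one-node configuration loses to the default
  degenerate <- DnnConfig(layerSizes = 1L, seed = 1L, maxEpochs = 2L,
    learningRate = 1e-6)
  good <- DnnConfig(seed = 1L, maxEpochs = 10L)
  g2 <- gridSearchDnn(list(degenerate, good), X, y, fit$val$X, fit$val$y)
  expect_identical(g2$config@layerSizes, good@layerSizes)

  # identical configs tie; the first is returned
  twin <- DnnConfig(seed = 5L, maxEpochs = 2L)
  g3 <- gridSearchDnn(list(twin, twin), X, y, fit$val$X, fit$val$y)
  expect_equal(g3$results$valAuc[1], g3$results$valAuc[2])
  expect_identical(g3$config, twin)
})

test_that("a saved model reloads bitwise", {
  fit <- smallSeparableFit()
  d <- withr::local_tempdir()
  saveDisorderModel(fit$model, d)
  back <- loadDisorderModel(d)
  expect_identical(back@kind, fit$model@kind)
  expect_identical(back@threshold, fit$model@threshold)
  expect_identical(
    predictPropensity(back, fit$val$X),
    predictPropensity(fit$model, fit$val$X)
  )
  lr <- trainDisorderModel(fit$train$X[1:400, ], fit$train$y[1:400],
    fit$val$X, fit$val$y, quickDnn(), kind = "logistic")
  d2 <- withr::local_tempdir()
  saveDisorderModel(lr, d2)
  expect_identical(
    predictPropensity(loadDisorderModel(d2), fit$val$X),
    predictPropensity(lr, fit$val$X)
  )
})

test_that("labels independent of the channels give chance-level AUC", {
  aucs <- numeric(20)
  for (i in seq_len(20)) {
    ds <- simulateDataset(SimParams(
      nProteins = 30L, lengthRange = c(40L, 60L),
      channelEffects = list(), proteinBiasSd = 0.05,
      noiseSd = 0.1, seed = 300L + i
    ))
    sp <- splitDataset(ds, seed = i)
    sc <- defaultSchema()
    enc <- disorderEncodingConfig()
    tr <- encodeDataset(sp$train$profiles, enc, sc)
    va <- encodeDataset(sp$validation$profiles, enc, sc)
    te <- encodeDataset(sp$test$profiles, enc, sc)
    m <- trainDisorderModel(
      tr, unlist(disorderTracks(sp$train)[names(sp$train$profiles)]),
      va, unlist(disorderTracks(sp$validation)[names(sp$validation$profiles)]),
      DnnConfig(seed = i, maxEpochs = 12L)
    )
    teY <- unlist(disorderTracks(sp$test)[names(sp$test$profiles)])
    aucs[i] <- fldpr::rocAuc(predictPropensity(m, te), teY)$auc
  }
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
})
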