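test_that("function training rows are the predicted-disordered residues", {
  sc <- defaultSchema()
  set.seed(50)
  pr <- randomProfile(10L, "p1", sc)
  ann <- data.frame(protein_id = "p1", start = 1L, end = 5L,
    label = "protein_binding")
  ts <- buildFunctionTrainingSet(
    list(p1 = pr), list(p1 = rep(1L, 10)), ann, "protein_binding"
  )
  expect_equal(nrow(ts$features), 10L)
  expect_equal(ts$labels, c(rep(1L, 5), rep(0L, 5)))
  expect_equal(ncol(ts$features), 138L) # 3P + 3 function encoding

  # a fully structured protein contributes no rows
  ts2 <- buildFunctionTrainingSet(
    list(p1 = pr, p2 = randomProfile(8L, "p2", sc)),
    list(p1 = rep(1L, 10), p2 = rep(0L, 8)),
    ann, "protein_binding"
  )
  expect_equal(nrow(ts2$features), 10L)

  # annotation outside every predicted IDR gives all-zero labels
  ann3 <- data.frame(protein_id = "p1", start = 8L, end = 10L,
    label = "protein_binding")
  ts3 <- buildFunctionTrainingSet(
    list(p1 = pr), list(p1 = c(rep(1L, 5), rep(0L, 5))), ann3,
    "protein_binding"
  )
  expect_equal(nrow(ts3$features), 5L)
  expect_true(all(ts3$labels == 0L))

  expect_error(
    buildFunctionTrainingSet(list(p1 = pr), list(p1 = rep(0L, 10)), ann,
      "protein_binding"),
    "no predicted-disordered"
  )
})

test_that("a planted single-channel function signal is learned", {
  ds <- miniFunctionData()
  ids <- names(ds$profiles)
  trainIds <- ids[1:35]
  testIds <- ids[36:50]
  ts <- buildFunctionTrainingSet(
    ds$profiles[trainIds], ds$disorderBinary[trainIds],
    ds$annotations, "protein_binding"
  )
  m <- trainFunctionModel(ts, "protein_binding", quickRf())
  held <- buildFunctionTrainingSet(
    ds$profiles[testIds], ds$disorderBinary[testIds],
    ds$annotations, "protein_binding"
  )
  p <- numeric(nrow(held$features))
  for (id in unique(held$proteinId)) {
    sel <- held$proteinId == id
    fx <- predictFunctions(
      list(protein_binding = m, dna_binding = m, rna_binding = m,
        linker = m),
      ds$profiles[[id]], ds$disorderBinary[[id]]
    )
    p[sel] <- fx$propensity[ds$disorderBinary[[id]] == 1L,
      "protein_binding"]
  }
  expect_gte(fldpr::rocAuc(p, held$labels)$auc, 0.9)

  # the model's forest ranks its own channel's features highest
  imp <- sort(m@forest$variable.importance, decreasing = TRUE)
  expect_true(grepl("disordpbind_prot", names(imp)[1]))
})

test_that("a grid of one point is selected as-is; seeds give determinism", {
  ds <- miniFunctionData()
  ids <- names(ds$profiles)[1:20]
  ts <- buildFunctionTrainingSet(
    ds$profiles[ids], ds$disorderBinary[ids], ds$annotations, "linker"
  )
  cfg <- RfConfig(nTreesGrid = 100L, maxDepthGrid = 5L, seed = 2L)
  m1 <- trainFunctionModel(ts, "linker", cfg)
  expect_equal(nrow(m1@gridLog), 1L)
  m2 <- trainFunctionModel(ts, "linker", cfg)
  expect_identical(m1@threshold, m2@threshold)
  expect_identical(
    rev(sort(m1@forest$variable.importance))[1:5],
    rev(sort(m2@forest$variable.importance))[1:5]
  )
})

test_that("shuffled labels give chance-level cross-validated AUC", {
  ds <- miniFunctionData()
  ids <- names(ds$profiles)[1:25]
  ts <- buildFunctionTrainingSet(
    ds$profiles[ids], ds$disorderBinary[ids], ds$annotations,
    "protein_binding"
  )
  cvAucs <- numeric(20)
  for (i in seq_len(20)) {
    set.seed(400 + i)
    shuffled <- ts
    shuffled$labels <- sample(ts$labels)
    m <- trainFunctionModel(
      shuffled, "protein_binding",
      RfConfig(nTreesGrid = 100L, maxDepthGrid = 5L, seed = i)
    )
    cvAucs[i] <- m@gridLog$cvAuc[1]
  }
  expect_gte(mean(cvAucs), 0.4)
  expect_lte(mean(cvAucs), 0.6)
})

test_that("function predictions are masked to predicted disorder", {
  ds <- miniFunctionData()
  ids <- names(ds$profiles)[1:20]
  models <- miniFunctionModels()
  pr <- ds$profiles[[ids[1]]]
  L <- nrow(profileValues(pr))

  # fully structured prediction: all four tracks identically zero
  fx0 <- predictFunctions(models, pr, rep(0L, L))
  expect_true(all(fx0$propensity == 0))
  expect_true(all(fx0$binary == 0L))

  # IDR 1-3 of a length-5 window: non-zero only inside
  bin <- c(rep(1L, 3), rep(0L, L - 3))
  fx <- predictFunctions(models, pr, bin)
  expect_true(all(fx$propensity[4:L, ] == 0))
  expect_true(all(fx$binary[4:L, ] == 0L))
  expect_true(any(fx$propensity[1:3, ] > 0))

  # alignment invariant: function-positive implies disorder-positive
  expect_true(all(bin[which(fx$binary == 1L, arr.ind = TRUE)[, 1]] == 1L))

  expect_error(
    predictFunctions(models[1:3], pr, bin),
    "missing function model"
  )
})

test_that("the four models are independent of each other's annotations", {
  ds <- miniFunctionData()
  ids <- names(ds$profiles)[1:20]
  full <- miniFunctionModels()
  annNoLinker <- ds$annotations[ds$annotations$label != "linker", ]
  # linker becomes single-class without its annotations; train the others
  others <- setdiff(functionLabels(), "linker")
  refit <- lapply(others, function(f) {
    ts <- buildFunctionTrainingSet(
      ds$profiles[ids], ds$disorderBinary[ids], annNoLinker, f
    )
    trainFunctionModel(ts, f, quickRf())
  })
  names(refit) <- others
  pr <- ds$profiles[[ids[2]]]
  bin <- ds$disorderBinary[[ids[2]]]
  fxFull <- predictFunctions(full, pr, bin)
  refit$linker <- full$linker
  fxRefit <- predictFunctions(refit, pr, bin)
  for (f in others) {
    expect_equal(fxRefit$propensity[, f], fxFull$propensity[, f])
  }
})

test_that("single-class function labels are rejected", {
  ds <- miniFunctionData()
  ids <- names(ds$profiles)[1:5]
  ts <- buildFunctionTrainingSet(
    ds$profiles[ids], ds$disorderBinary[ids], ds$annotations,
    "protein_binding"
  )
  ts$labels <- rep(0L, length(ts$labels))
  expect_error(trainFunctionModel(ts, "protein_binding", quickRf()),
    "single class")
})
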