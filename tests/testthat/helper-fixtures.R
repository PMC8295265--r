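# session-level cache so expensive fixtures/models are built once
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# profile with every channel constant c
constProfile <- function(L, c = 0.5, id = "const",
                         schema = defaultSchema()) {
  m <- matrix(c, nrow = L, ncol = length(channels(schema)),
    dimnames = list(NULL, channels(schema)))
  Profile(id, m, schema)
}

# small random profile respecting [0,1] ranges
randomProfile <- function(L, id = "rand", schema = defaultSchema()) {
  m <- matrix(stats::runif(L * length(channels(schema))), nrow = L,
    dimnames = list(NULL, channels(schema)))
  Profile(id, m, schema)
}

# the full fixture suite at the session seed (built once)
fixtures <- function() cached("fixtures", fixtureSuite(seed = 1L))

# a small separable dataset for quick model tests
smallSeparable <- function() {
  cached("smallSeparable", simulateDataset(SimParams(
    nProteins = 60L, lengthRange = c(40L, 80L),
    proteinBiasSd = 0.05, fullyDisorderedFraction = 0.05,
    channelEffects = list(disorder = c(iupred_long = 1.0)),
    noiseSd = 0.1, seed = 11L
  )))
}

# quick training configuration used across model tests
quickDnn <- function(seed = 1L, maxEpochs = 40L) {
  DnnConfig(seed = seed, maxEpochs = maxEpochs)
}

# disorder model trained on the small separable dataset (built once)
smallSeparableFit <- function() {
  cached("smallSeparableFit", {
    sp <- splitDataset(smallSeparable(), seed = 1L)
    enc <- disorderEncodingConfig()
    sc <- defaultSchema()
    tr <- list(
      X = encodeDataset(sp$train$profiles, enc, sc),
      y = unlist(disorderTracks(sp$train)[names(sp$train$profiles)])
    )
    va <- list(
      X = encodeDataset(sp$validation$profiles, enc, sc),
      y = unlist(disorderTracks(sp$validation)[names(sp$validation$profiles)])
    )
    model <- trainDisorderModel(tr$X, tr$y, va$X, va$y, quickDnn())
    list(splits = sp, train = tr, val = va, model = model)
  })
}

# small dataset with one dedicated signal channel per function; the truth
# disorder tracks stand in for the disorder model's binary output
miniFunctionData <- function() {
  cached("miniFunctionData", {
    ds <- simulateDataset(SimParams(
      nProteins = 50L, lengthRange = c(40L, 80L),
      proteinBiasSd = 0.05, fullyDisorderedFraction = 0.05,
      channelEffects = list(
        disorder = c(iupred_long = 1.0),
        protein_binding = c(disordpbind_prot = 0.8),
        dna_binding = c(disordpbind_dna = 0.8),
        rna_binding = c(disordpbind_rna = 0.8),
        linker = c(dflpred = 0.8)
      ),
      noiseSd = 0.1, seed = 21L
    ))
    ds$disorderBinary <- disorderTracks(ds)
    ds
  })
}

quickRf <- function(seed = 1L) {
  RfConfig(nTreesGrid = 100L, maxDepthGrid = c(5L, 0L), seed = seed)
}

miniFunctionModels <- function() {
  ds <- miniFunctionData()
  ids <- names(ds$profiles)[1:20]
  cached("miniFunctionModels", trainFunctionModels(
    ds$profiles[ids], ds$disorderBinary[ids], ds$annotations,
    config = quickRf()
  ))
}

# brute-force AUC oracle: fraction of correctly ordered positive-negative
# pairs, ties counted half
pairOrderAuc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
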