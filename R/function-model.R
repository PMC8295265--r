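#' Random-forest grid-search configuration for function models
#'
#' @param nTreesGrid forest sizes (default 100/250/500).
#' @param maxDepthGrid tree depths, 0 = unlimited (default 5/10/0).
#' @param cvFolds cross-validation folds scoring the grid (default 3).
#' @param seed integer seed.
#' @return An [RfConfig-class].
#' @export
RfConfig <- function(nTreesGrid = c(100L, 250L, 500L),
                     maxDepthGrid = c(5L, 10L, 0L),
                     cvFolds = 3L, seed = 1L) {
  new("RfConfig",
    nTreesGrid = as.integer(nTreesGrid),
    maxDepthGrid = as.integer(maxDepthGrid),
    cvFolds = as.integer(cvFolds), seed = as.integer(seed)
  )
}

#' Assemble the training set for one disorder function
#'
#' Function models are trained only on residues inside putative
#' disordered regions — the residues the disorder model called
#' disordered. A residue is a positive when it lies in a region
#' annotated with the requested function; all other predicted-disordered
#' residues are negatives. Features use the function-task encoding
#' (residue window 1, averaging window 11).
#'
#' @param profiles named list of [Profile-class] objects.
#' @param disorderBinary named list of 0/1 tracks from the disorder
#'   model, aligned with `profiles`.
#' @param annotations region annotation data.frame.
#' @param functionLabel one of [functionLabels()].
#' @param schema a [ProfileSchema-class].
#' @param config function-task [EncodingConfig-class].
#' @return List with `features` (matrix over predicted-disordered
#'   residues), `labels`, `proteinId` (per row) and `fingerprint`.
#' @export
buildFunctionTrainingSet <- function(profiles, disorderBinary, annotations,
                                     functionLabel,
                                     schema = defaultSchema(),
                                     config = functionEncodingConfig()) {
  stopifnot(functionLabel %in% functionLabels())
  ids <- vapply(profiles, proteinId, character(1))
  names(profiles) <- ids
  miss <- setdiff(ids, names(disorderBinary))
  if (length(miss)) {
    stop("no disorder prediction for protein(s): ",
      paste(miss, collapse = ", "))
  }
  feats <- list()
  labs <- list()
  rows <- list()
  for (id in ids) {
    mask <- disorderBinary[[id]] == 1L
    if (!any(mask)) next
    X <- encodeProfile(profiles[[id]], config, schema)
    y <- regionsToTrack(annotations, functionLabel, id, nrow(X))
    feats[[id]] <- X[mask, , drop = FALSE]
    labs[[id]] <- y[mask]
    rows[[id]] <- rep(id, sum(mask))
  }
  if (length(feats) == 0L) {
    stop("no predicted-disordered residues in the training set")
  }
  out <- do.call(rbind, feats)
  attr(out, "fingerprint") <- encodingFingerprint(config, schema)
  list(
    features = out,
    labels = unlist(labs, use.names = FALSE),
    proteinId = unlist(rows, use.names = FALSE),
    fingerprint = encodingFingerprint(config, schema)
  )
}

rangerFit <- function(X, y, nTrees, maxDepth, seed) {
  df <- data.frame(y = factor(y, levels = c(0L, 1L)), X, check.names = FALSE)
  ranger::ranger(
    y ~ ., data = df,
    num.trees = nTrees,
    max.depth = if (maxDepth == 0L) NULL else maxDepth,
    probability = TRUE,
    importance = "impurity",
    seed = seed,
    num.threads = 1L
  )
}

rangerProb <- function(forest, X) {
  pr <- stats::predict(forest, data.frame(X, check.names = FALSE),
    num.threads = 1L)$predictions
  as.numeric(pr[, "1"])
}

#' Train the random-forest model for one disorder function
#'
#' Every (trees, depth) grid point is scored by the mean ROC-AUC over
#' k-fold cross-validation of the training rows; the winning grid point
#' (ties toward earlier grid order) is refit on all rows, and the binary
#' threshold is chosen by [selectThreshold()] on the winning point's
#' out-of-fold predictions. Deterministic given `config@seed`.
#'
#' @param trainingSet list from [buildFunctionTrainingSet()].
#' @param functionLabel one of [functionLabels()].
#' @param config an [RfConfig-class].
#' @return A [FunctionModel-class].
#' @export
trainFunctionModel <- function(trainingSet, functionLabel,
                               config = RfConfig()) {
  X <- trainingSet$features
  y <- as.integer(trainingSet$labels)
  if (length(unique(y)) < 2L) {
    stop("function training labels contain a single class")
  }
  n <- length(y)
  k <- config@cvFolds
  set.seed(config@seed)
  folds <- sample(rep_len(seq_len(k), n))
  grid <- expand.grid(
    nTrees = config@nTreesGrid, maxDepth = config@maxDepthGrid
  )
  cvAuc <- numeric(nrow(grid))
  oof <- matrix(NA_real_, nrow = n, ncol = nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) {
        aucs[f] <- NA_real_
        next
      }
      fit <- rangerFit(
        X[tr, , drop = FALSE], y[tr],
        grid$nTrees[g], grid$maxDepth[g], config@seed + f
      )
      p <- rangerProb(fit, X[!tr, , drop = FALSE])
      oof[!tr, g] <- p
      aucs[f] <- fastAuc(p, y[!tr])
    }
    cvAuc[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cvAuc) # first max = earliest grid point on ties
  forest <- rangerFit(X, y, grid$nTrees[best], grid$maxDepth[best],
    config@seed)
  oofBest <- oof[, best]
  ok <- !is.na(oofBest)
  thr <- if (any(ok) && length(unique(y[ok])) >= 2L) {
    as.numeric(selectThreshold(oofBest[ok], y[ok]))
  } else {
    0.5
  }
  new("FunctionModel",
    functionLabel = functionLabel,
    forest = forest,
    threshold = thr,
    fingerprint = trainingSet$fingerprint %||% "",
    gridLog = data.frame(grid, cvAuc = cvAuc)
  )
}

#' Train all four function models
#'
#' @inheritParams buildFunctionTrainingSet
#' @param config an [RfConfig-class].
#' @return Named list of four [FunctionModel-class] objects.
#' @export
trainFunctionModels <- function(profiles, disorderBinary, annotations,
                                schema = defaultSchema(),
                                config = RfConfig()) {
  out <- lapply(functionLabels(), function(f) {
    ts <- buildFunctionTrainingSet(
      profiles, disorderBinary, annotations, f, schema
    )
    trainFunctionModel(ts, f, config)
  })
  names(out) <- functionLabels()
  out
}

#' Predict function tracks aligned with the disorder prediction
#'
#' Function propensities are produced only inside predicted disordered
#' regions; outside them the propensity is reported as 0 and the binary
#' call as 0. This masking guarantees that no residue is ever
#' function-positive while being called structured — the predictions
#' cannot contradict each other by construction.
#'
#' @param models named list of the four [FunctionModel-class] objects.
#' @param profile a [Profile-class].
#' @param disorderBinary 0/1 track from the disorder model on the same
#'   profile.
#' @param schema a [ProfileSchema-class].
#' @param config function-task [EncodingConfig-class].
#' @return List with `propensity` and `binary`, each an L x 4 matrix
#'   (columns [functionLabels()]).
#' @export
predictFunctions <- function(models, profile, disorderBinary,
                             schema = defaultSchema(),
                             config = functionEncodingConfig()) {
  fl <- functionLabels()
  miss <- setdiff(fl, names(models))
  if (length(miss)) {
    stop("missing function model(s): ", paste(miss, collapse = ", "))
  }
  L <- nrow(profile@values)
  stopifnot(length(disorderBinary) == L)
  prop <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, fl))
  bin <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, fl))
  idr <- which(disorderBinary == 1L)
  if (length(idr)) {
    X <- encodeProfile(profile, config, schema)
    fp <- attr(X, "fingerprint")
    for (f in fl) {
      m <- models[[f]]
      if (nzchar(m@fingerprint) && m@fingerprint != fp) {
        stop("encoding fingerprint mismatch for function model ", f)
      }
      p <- rangerProb(m@forest, X[idr, , drop = FALSE])
      prop[idr, f] <- p
      bin[idr, f] <- binarize(p, m@threshold)
    }
  }
  list(propensity = prop, binary = bin)
}
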