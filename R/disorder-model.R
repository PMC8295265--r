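#' Construct a disorder-network configuration
#'
#' Defaults mirror the deployed architecture: input layer as wide as the
#' feature vector (318 under the default schema and disorder encoding),
#' dropout 0.2 after the input and after the first hidden layer, hidden
#' layers of 64 and 8 ReLU nodes, one sigmoid output node. Training is
#' adaptive-moment gradient descent on a class-weighted binary
#' cross-entropy, early-stopped on validation ROC-AUC.
#'
#' @param layerSizes hidden-layer widths.
#' @param dropout dropout rate.
#' @param inputDim expected feature width (0 = inferred at fit time).
#' @param seed integer seed for weight init, shuffling and dropout.
#' @param maxEpochs,patience,batchSize,learningRate training controls.
#' @return A [DnnConfig-class].
#' @export
DnnConfig <- function(layerSizes = c(64L, 8L), dropout = 0.2,
                      inputDim = 0L, seed = 1L, maxEpochs = 200L,
                      patience = 10L, batchSize = 256L,
                      learningRate = 1e-3) {
  new("DnnConfig",
    layerSizes = as.integer(layerSizes), dropout = dropout,
    inputDim = as.integer(inputDim), seed = as.integer(seed),
    maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
    batchSize = as.integer(batchSize), learningRate = learningRate
  )
}

relu <- function(x) x * (x > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlpInit <- function(inputDim, layerSizes) {
  dims <- c(inputDim, layerSizes, 1L)
  W <- vector("list", length(dims) - 1L)
  b <- vector("list", length(dims) - 1L)
  for (l in seq_along(W)) {
    fanIn <- dims[l]
    W[[l]] <- matrix(
      stats::rnorm(fanIn * dims[l + 1L], sd = sqrt(2 / fanIn)),
      nrow = fanIn
    )
    b[[l]] <- numeric(dims[l + 1L])
  }
  list(W = W, b = b)
}

# forward pass; training = TRUE draws inverted-dropout masks from the
# current RNG stream (after the input and after the first hidden layer)
mlpForward <- function(params, X, dropout = 0, training = FALSE) {
  nl <- length(params$W)
  A <- X
  cache <- list(A0 = X, masks = vector("list", nl))
  if (training && dropout > 0) {
    m <- matrix(
      stats::rbinom(length(A), 1L, 1 - dropout) / (1 - dropout),
      nrow = nrow(A)
    )
    A <- A * m
    cache$masks[[1L]] <- m
    cache$A0 <- A
  }
  cache$Z <- cache$A <- vector("list", nl)
  for (l in seq_len(nl)) {
    Z <- sweep(A %*% params$W[[l]], 2L, params$b[[l]], "+")
    if (l < nl) {
      A <- relu(Z)
      if (training && dropout > 0 && l == 1L) {
        m <- matrix(
          stats::rbinom(length(A), 1L, 1 - dropout) / (1 - dropout),
          nrow = nrow(A)
        )
        A <- A * m
        cache$masks[[l + 1L]] <- m
      }
    } else {
      A <- sigmoid(Z)
    }
    cache$Z[[l]] <- Z
    cache$A[[l]] <- A
  }
  cache$out <- as.numeric(A)
  cache
}

mlpGradients <- function(params, cache, y, w) {
  nl <- length(params$W)
  n <- length(y)
  gW <- vector("list", nl)
  gb <- vector("list", nl)
  # weighted BCE with sigmoid output: dL/dZ_out = w * (p - y) / n
  delta <- matrix(w * (cache$out - y) / n, ncol = 1L)
  for (l in rev(seq_len(nl))) {
    Aprev <- if (l == 1L) cache$A0 else cache$A[[l - 1L]]
    gW[[l]] <- crossprod(Aprev, delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(params$W[[l]])) * (cache$Z[[l - 1L]] > 0)
      if (!is.null(cache$masks[[l]])) {
        delta <- delta * cache$masks[[l]]
      }
    }
  }
  list(W = gW, b = gb)
}

adamStep <- function(params, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in seq_along(params$W)) {
    for (slot in c("W", "b")) {
      g <- grads[[slot]][[l]]
      state$m[[slot]][[l]] <- beta1 * state$m[[slot]][[l]] + (1 - beta1) * g
      state$v[[slot]][[l]] <- beta2 * state$v[[slot]][[l]] +
        (1 - beta2) * g^2
      mhat <- state$m[[slot]][[l]] / (1 - beta1^t)
      vhat <- state$v[[slot]][[l]] / (1 - beta2^t)
      params[[slot]][[l]] <- params[[slot]][[l]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Train a disorder model
#'
#' Fits either the deep feedforward network (`kind = "dnn"`) or its
#' logistic-regression twin (`kind = "logistic"`) on per-residue feature
#' rows. The network minimises a class-weighted (inverse-frequency)
#' binary cross-entropy with adaptive-moment updates, evaluating
#' validation ROC-AUC after every epoch and keeping the best-epoch
#' weights (early stop after `patience` epochs without improvement).
#' The binary-call threshold is then selected on the validation set by
#' [selectThreshold()]. Fully deterministic given `config@seed`.
#'
#' @param features training feature matrix (rows = residues).
#' @param labels 0/1 vector, one per training row.
#' @param valFeatures,valLabels validation set in the same layout.
#' @param config a [DnnConfig-class].
#' @param kind `"dnn"` or `"logistic"`.
#' @return A [DisorderModel-class] with threshold set.
#' @export
trainDisorderModel <- function(features, labels, valFeatures, valLabels,
                               config = DnnConfig(), kind = "dnn") {
  stopifnot(kind %in% c("dnn", "logistic"))
  y <- as.integer(labels)
  yv <- as.integer(valLabels)
  if (nrow(features) != length(y) || nrow(valFeatures) != length(yv)) {
    stop("feature rows and labels differ in length")
  }
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class")
  }
  if (config@inputDim > 0L && config@inputDim != ncol(features)) {
    stop(
      "input_dim mismatch: config expects ", config@inputDim,
      " features, got ", ncol(features)
    )
  }
  fp <- attr(features, "fingerprint")
  if (is.null(fp)) fp <- ""
  d <- ncol(features)
  # inverse-frequency class weights
  n <- length(y)
  w <- ifelse(y == 1L, n / (2 * sum(y == 1L)), n / (2 * sum(y == 0L)))

  if (kind == "logistic") {
    set.seed(config@seed)
    fit <- glmnet::glmnet(
      features, y,
      family = "binomial", alpha = 0, lambda = 1e-4,
      weights = w, standardize = TRUE
    )
    beta <- as.numeric(stats::coef(fit, s = 1e-4))
    pv <- as.numeric(sigmoid(cbind(1, valFeatures) %*% beta))
    model <- new("DisorderModel",
      kind = "logistic",
      params = list(beta = beta),
      threshold = NA_real_,
      inputDim = d,
      fingerprint = fp,
      config = config,
      log = data.frame(epoch = 1L, valAuc = fastAuc(pv, yv))
    )
  } else {
    set.seed(config@seed)
    params <- mlpInit(d, config@layerSizes)
    zeroLike <- lapply(params, function(x) lapply(x, function(z) z * 0))
    state <- list(m = zeroLike, v = zeroLike)
    best <- list(auc = -Inf, params = params, epoch = 0L)
    t <- 0L
    trace <- data.frame(epoch = integer(0), valAuc = numeric(0))
    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config@batchSize)
      for (s in starts) {
        idx <- ord[s:min(s + config@batchSize - 1L, n)]
        cache <- mlpForward(
          params, features[idx, , drop = FALSE],
          dropout = config@dropout, training = TRUE
        )
        grads <- mlpGradients(params, cache, y[idx], w[idx])
        t <- t + 1L
        upd <- adamStep(params, grads, state, config@learningRate, t)
        params <- upd$params
        state <- upd$state
      }
      pv <- mlpForward(params, valFeatures)$out
      auc <- fastAuc(pv, yv)
      trace <- rbind(trace, data.frame(epoch = epoch, valAuc = auc))
      if (!is.na(auc) && auc > best$auc) {
        best <- list(auc = auc, params = params, epoch = epoch)
      }
      if (epoch - best$epoch >= config@patience) break
    }
    model <- new("DisorderModel",
      kind = "dnn",
      params = best$params,
      threshold = NA_real_,
      inputDim = d,
      fingerprint = fp,
      config = config,
      log = trace
    )
  }
  pv <- predictPropensity(model, valFeatures)
  model@threshold <- if (length(unique(yv)) >= 2L) {
    as.numeric(selectThreshold(pv, yv))
  } else {
    0.5
  }
  methods::validObject(model)
  model
}

#' Grid search over network configurations
#'
#' Trains one model per configuration and returns the configuration
#' whose model maximises validation ROC-AUC; ties are broken toward
#' fewer parameters, then earlier position in the grid.
#'
#' @param configs list of [DnnConfig-class] objects.
#' @inheritParams trainDisorderModel
#' @return List with `config` (the winner), `model`, and `results`
#'   (data.frame of per-config validation AUC and parameter counts).
#' @export
gridSearchDnn <- function(configs, features, labels, valFeatures,
                          valLabels, kind = "dnn") {
  stopifnot(length(configs) >= 1L)
  d <- ncol(features)
  nPar <- vapply(configs, function(cf) {
    dims <- c(d, cf@layerSizes, 1L)
    sum((dims[-length(dims)] + 1L) * dims[-1L])
  }, numeric(1))
  models <- lapply(configs, function(cf) {
    trainDisorderModel(features, labels, valFeatures, valLabels, cf, kind)
  })
  auc <- vapply(models, function(m) max(m@log$valAuc), numeric(1))
  ord <- order(-auc, nPar, seq_along(configs))
  best <- ord[1L]
  list(
    config = configs[[best]],
    model = models[[best]],
    results = data.frame(
      config = seq_along(configs), valAuc = auc, nParameters = nPar
    )
  )
}

#' Per-residue disorder propensities
#'
#' Applies a trained model (dropout disabled) to a feature matrix; when
#' both the model and the features carry an encoding fingerprint they
#' must agree.
#'
#' @param model a [DisorderModel-class].
#' @param features feature matrix with `ncol == model@inputDim`.
#' @return Numeric vector of propensities in [0, 1], one per row.
#' @export
predictPropensity <- function(model, features) {
  if (ncol(features) != model@inputDim) {
    stop(
      "feature dimension ", ncol(features),
      " does not match model input dim ", model@inputDim
    )
  }
  fp <- attr(features, "fingerprint")
  if (!is.null(fp) && nzchar(model@fingerprint) && fp != model@fingerprint) {
    stop("encoding fingerprint mismatch between model and features")
  }
  if (model@kind == "logistic") {
    as.numeric(sigmoid(cbind(1, features) %*% model@params$beta))
  } else {
    mlpForward(model@params, features)$out
  }
}

#' Select the binary-call threshold on a validation set
#'
#' Candidate thresholds are the unique propensity values; each candidate
#' is scored by the F1 of calling positive at or above it, and the
#' best-scoring candidate is returned (ties toward the smaller value).
#'
#' @param propensities numeric vector.
#' @param labels 0/1 vector; both classes must be present.
#' @return The selected threshold, with the achieved F1 as attribute
#'   `"f1"`.
#' @examples
#' selectThreshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.35
#' @export
selectThreshold <- function(propensities, labels) {
  y <- as.integer(unlist(labels, use.names = FALSE))
  p <- as.numeric(unlist(propensities, use.names = FALSE))
  if (length(unique(y)) < 2L) stop("threshold selection needs both classes")
  cand <- sort(unique(p))
  nPos <- sum(y == 1L)
  # predicting positive where p >= t
  f1 <- vapply(cand, function(t) {
    pred <- p >= t
    tp <- sum(pred & y == 1L)
    fp <- sum(pred & y == 0L)
    fn <- nPos - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  best <- which.max(f1) # first max = smallest candidate on ties
  structure(cand[best], f1 = f1[best])
}

#' Binary calls from propensities
#'
#' A residue is called disordered when its propensity is strictly
#' greater than the threshold.
#'
#' @param propensities numeric vector.
#' @param threshold cutoff in [0, 1].
#' @return Integer 0/1 vector.
#' @examples
#' binarize(c(0.2, 0.5, 0.9), 0.5) # 0 0 1
#' @export
binarize <- function(propensities, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  as.integer(propensities > threshold)
}

#' Save / load a disorder model directory
#'
#' The model is stored as a directory of plain-text files: a JSON of the
#' configuration, threshold and encoding fingerprint, and one TSV per
#' parameter array at full precision, so a save/load round trip
#' reproduces propensities bitwise on the same platform.
#'
#' @param model a [DisorderModel-class].
#' @param dir directory path (created if needed).
#' @return `saveDisorderModel` returns `dir` invisibly;
#'   `loadDisorderModel` returns the model.
#' @export
saveDisorderModel <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cf <- model@config
  meta <- list(
    kind = model@kind,
    threshold = model@threshold,
    inputDim = model@inputDim,
    fingerprint = model@fingerprint,
    config = list(
      layerSizes = cf@layerSizes, dropout = cf@dropout,
      inputDim = cf@inputDim, seed = cf@seed, maxEpochs = cf@maxEpochs,
      patience = cf@patience, batchSize = cf@batchSize,
      learningRate = cf@learningRate
    )
  )
  jsonlite::write_json(
    meta, file.path(dir, "model.json"),
    auto_unbox = TRUE, digits = NA
  )
  writeArray <- function(x, name) {
    utils::write.table(
      formatC(as.matrix(x), format = "g", digits = 17),
      file.path(dir, paste0(name, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  if (model@kind == "logistic") {
    writeArray(model@params$beta, "beta")
  } else {
    for (l in seq_along(model@params$W)) {
      writeArray(model@params$W[[l]], paste0("W", l))
      writeArray(model@params$b[[l]], paste0("b", l))
    }
  }
  utils::write.table(
    model@log, file.path(dir, "training_log.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}

#' @rdname saveDisorderModel
#' @export
loadDisorderModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
    simplifyVector = TRUE)
  cf <- DnnConfig(
    layerSizes = meta$config$layerSizes, dropout = meta$config$dropout,
    inputDim = meta$config$inputDim, seed = meta$config$seed,
    maxEpochs = meta$config$maxEpochs, patience = meta$config$patience,
    batchSize = meta$config$batchSize,
    learningRate = meta$config$learningRate
  )
  readArray <- function(name) {
    as.matrix(utils::read.table(
      file.path(dir, paste0(name, ".tsv")),
      sep = "\t", colClasses = "numeric"
    ))
  }
  if (meta$kind == "logistic") {
    params <- list(beta = as.numeric(readArray("beta")))
  } else {
    nl <- length(meta$config$layerSizes) + 1L
    params <- list(W = vector("list", nl), b = vector("list", nl))
    for (l in seq_len(nl)) {
      params$W[[l]] <- unname(readArray(paste0("W", l)))
      params$b[[l]] <- as.numeric(readArray(paste0("b", l)))
    }
  }
  lg <- utils::read.delim(file.path(dir, "training_log.tsv"))
  new("DisorderModel",
    kind = meta$kind, params = params,
    threshold = as.numeric(meta$threshold),
    inputDim = as.integer(meta$inputDim),
    fingerprint = meta$fingerprint %||% "",
    config = cf, log = lg
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
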