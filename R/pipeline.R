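#' Per-residue disorder labels for a dataset
#'
#' @param dataset list with `proteins` and `annotations` (as produced by
#'   [simulateDataset()] or [readDataset()]).
#' @return Named list of 0/1 tracks.
#' @export
disorderTracks <- function(dataset) {
  labelTracks(dataset$annotations, "disorder", dataset$proteins)
}

datasetXY <- function(dataset, config, schema) {
  X <- encodeDataset(dataset$profiles, config, schema)
  tracks <- disorderTracks(dataset)
  y <- unlist(tracks[names(dataset$profiles)], use.names = FALSE)
  stopifnot(nrow(X) == length(y))
  list(X = X, y = y, tracks = tracks)
}

#' Train the full predictor on train/validation datasets
#'
#' Encodes both datasets under the disorder-task encoding, trains the
#' disorder network (and optionally the logistic twin), then trains the
#' four function random forests on the residues the disorder model
#' calls disordered in the training set.
#'
#' @param trainData,valData dataset lists (`proteins`, `profiles`,
#'   `annotations`).
#' @param schema a [ProfileSchema-class].
#' @param dnnConfig a [DnnConfig-class].
#' @param rfConfig an [RfConfig-class].
#' @param withFunctions also train the four function models.
#' @return List with `disorder` ([DisorderModel-class]), `functions`
#'   (named list of [FunctionModel-class] or NULL), `schema`.
#' @export
trainPipeline <- function(trainData, valData, schema = defaultSchema(),
                          dnnConfig = DnnConfig(),
                          rfConfig = RfConfig(),
                          withFunctions = TRUE) {
  enc <- disorderEncodingConfig()
  tr <- datasetXY(trainData, enc, schema)
  va <- datasetXY(valData, enc, schema)
  disorder <- trainDisorderModel(tr$X, tr$y, va$X, va$y, dnnConfig)
  functions <- NULL
  if (withFunctions) {
    ids <- names(trainData$profiles)
    rows <- attr(tr$X, "proteinId")
    prop <- predictPropensity(disorder, tr$X)
    bin <- binarize(prop, disorder@threshold)
    disBin <- lapply(ids, function(id) bin[rows == id])
    names(disBin) <- ids
    functions <- trainFunctionModels(
      trainData$profiles, disBin, trainData$annotations, schema, rfConfig
    )
  }
  list(disorder = disorder, functions = functions, schema = schema)
}

#' Predict disorder and function tracks for proteins
#'
#' @param models list from [trainPipeline()] (or with `disorder` and
#'   optionally `functions`).
#' @param profiles named list of [Profile-class] objects.
#' @param proteins named sequence set aligned with `profiles`.
#' @return Named list of [PredictionResult-class] objects.
#' @export
predictProteins <- function(models, profiles, proteins) {
  schema <- models$schema %||% defaultSchema()
  enc <- disorderEncodingConfig()
  fl <- functionLabels()
  out <- lapply(names(profiles), function(id) {
    pr <- profiles[[id]]
    X <- encodeProfile(pr, enc, schema)
    prop <- predictPropensity(models$disorder, X)
    bin <- binarize(prop, models$disorder@threshold)
    if (!is.null(models$functions)) {
      fx <- predictFunctions(models$functions, pr, bin, schema)
    } else {
      L <- length(bin)
      fx <- list(
        propensity = matrix(0, L, 4L, dimnames = list(NULL, fl)),
        binary = matrix(0L, L, 4L, dimnames = list(NULL, fl))
      )
    }
    new("PredictionResult",
      proteinId = id,
      sequence = as.character(proteins[[id]]),
      disorderPropensity = prop,
      disorderBinary = bin,
      functionPropensity = fx$propensity,
      functionBinary = fx$binary
    )
  })
  names(out) <- names(profiles)
  out
}
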