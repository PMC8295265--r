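#' @import methods
NULL

#' Annotation labels understood by the package
#'
#' Per-residue annotations carry one of five labels: intrinsic disorder
#' itself, or one of the four disorder functions assigned within disordered
#' regions (protein binding, DNA binding, RNA binding, flexible linker).
#'
#' @return Character vector of the five labels; `functionLabels()` returns
#'   only the four function labels.
#' @examples
#' annotationLabels()
#' functionLabels()
#' @export
annotationLabels <- function() {
  c("disorder", functionLabels())
}

#' @rdname annotationLabels
#' @export
functionLabels <- function() {
  c("protein_binding", "dna_binding", "rna_binding", "linker")
}

#' ProfileSchema: named channel layout of a sequence profile
#'
#' A schema declares the ordered channel names of a per-residue profile,
#' the closed value range of each channel, and a partition of the channels
#' into named groups (used by the ablation machinery to drop whole input
#' families at once).
#'
#' @slot channels ordered character vector of unique channel names.
#' @slot ranges numeric matrix with rows `min`/`max` and one column per
#'   channel.
#' @slot groups named list partitioning `channels` into groups.
#' @seealso [defaultSchema()]
#' @export
setClass("ProfileSchema",
  representation(
    channels = "character",
    ranges = "matrix",
    groups = "list"
  )
)

setValidity("ProfileSchema", function(object) {
  ch <- object@channels
  if (length(ch) < 1L) return("schema must declare at least one channel")
  if (anyDuplicated(ch)) return("channel names must be unique")
  if (!identical(dim(object@ranges), c(2L, length(ch))))
    return("ranges must be a 2 x P matrix (rows min, max)")
  members <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(members))
    return("a channel may belong to only one group")
  if (!setequal(members, ch))
    return("groups must partition the channel set exactly")
  if (any(object@ranges[1L, ] > object@ranges[2L, ]))
    return("each channel range must satisfy min <= max")
  TRUE
})

#' Profile: per-residue channel matrix for one protein
#'
#' An L x P matrix of profile values, rows in sequence order and columns
#' following a [ProfileSchema-class]. Stands in for the concatenated
#' outputs of upstream sequence-analysis tools (PSSM, secondary structure,
#' disorder baselines, disorder-function predictors, physicochemical
#' scales).
#'
#' @slot proteinId protein identifier.
#' @slot values numeric matrix, one row per residue, column names equal to
#'   the schema channels.
#' @export
setClass("Profile",
  representation(
    proteinId = "character",
    values = "matrix"
  )
)

setValidity("Profile", function(object) {
  if (length(object@proteinId) != 1L || !nzchar(object@proteinId))
    return("proteinId must be a single non-empty string")
  v <- object@values
  if (nrow(v) < 1L) return("profile must have at least one residue row")
  if (is.null(colnames(v))) return("profile columns must be named")
  if (!all(is.finite(v))) return("profile values must all be finite")
  TRUE
})

#' EncodingConfig: three-level feature-encoding parameters
#'
#' Controls how a [Profile-class] is turned into per-residue feature
#' vectors: the width of the raw residue-level window, the width of the
#' averaging window, whether whole-protein summary features are appended,
#' and (for ablation) which schema groups or encoding levels are omitted.
#'
#' @slot residueWindow odd positive integer; raw values of this many
#'   centred positions are concatenated (5 for the disorder task, 1 for
#'   the function task).
#' @slot averageWindow odd positive integer; per-channel mean over this
#'   centred window (15 for the disorder task, 11 for the function task).
#' @slot includeProteinLevel append per-channel whole-chain means plus
#'   normalised length and the two terminus distances.
#' @slot excludedGroups schema group names dropped from all levels.
#' @slot excludedLevels subset of `c("residue", "window", "protein")`.
#' @seealso [disorderEncodingConfig()], [functionEncodingConfig()]
#' @export
setClass("EncodingConfig",
  representation(
    residueWindow = "integer",
    averageWindow = "integer",
    includeProteinLevel = "logical",
    excludedGroups = "character",
    excludedLevels = "character"
  ),
  prototype(
    residueWindow = 5L,
    averageWindow = 15L,
    includeProteinLevel = TRUE,
    excludedGroups = character(0),
    excludedLevels = character(0)
  )
)

setValidity("EncodingConfig", function(object) {
  r <- object@residueWindow
  a <- object@averageWindow
  if (length(r) != 1L || r < 1L || r %% 2L == 0L)
    return("residueWindow must be a single odd positive integer")
  if (length(a) != 1L || a < 1L || a %% 2L == 0L)
    return("averageWindow must be a single odd positive integer")
  if (r > a)
    return("residueWindow must not exceed averageWindow")
  lv <- object@excludedLevels
  if (!all(lv %in% c("residue", "window", "protein")))
    return("excludedLevels must be a subset of residue/window/protein")
  eff <- setdiff(c("residue", "window", "protein"), lv)
  if (!object@includeProteinLevel) eff <- setdiff(eff, "protein")
  if (length(eff) == 0L)
    return("at least one encoding level must remain active")
  TRUE
})

#' DnnConfig: architecture and training controls for the disorder network
#'
#' @slot layerSizes hidden-layer widths (default `c(64, 8)`); the output
#'   layer is always a single sigmoid unit.
#' @slot dropout dropout rate applied after the input and after the first
#'   hidden layer (default 0.2).
#' @slot inputDim expected feature-vector width (0 = set at training time).
#' @slot seed integer seed governing every stochastic training step.
#' @slot maxEpochs,patience,batchSize,learningRate optimisation controls:
#'   adaptive-moment gradient descent on a weighted binary cross-entropy,
#'   early-stopped on validation ROC-AUC.
#' @export
setClass("DnnConfig",
  representation(
    layerSizes = "integer",
    dropout = "numeric",
    inputDim = "integer",
    seed = "integer",
    maxEpochs = "integer",
    patience = "integer",
    batchSize = "integer",
    learningRate = "numeric"
  ),
  prototype(
    layerSizes = c(64L, 8L),
    dropout = 0.2,
    inputDim = 0L,
    seed = 1L,
    maxEpochs = 200L,
    patience = 10L,
    batchSize = 256L,
    learningRate = 1e-3
  )
)

setValidity("DnnConfig", function(object) {
  if (any(object@layerSizes < 1L))
    return("hidden layers must have at least one node")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (object@maxEpochs < 1L || object@patience < 1L || object@batchSize < 1L)
    return("maxEpochs, patience and batchSize must be positive")
  if (object@learningRate <= 0)
    return("learningRate must be positive")
  TRUE
})

#' DisorderModel: trained per-residue disorder predictor
#'
#' Holds either the deep feedforward network (`kind = "dnn"`) or its
#' logistic-regression twin (`kind = "logistic"`), the propensity
#' threshold used for binary calls, and the encoding fingerprint that ties
#' the model to the schema/encoding it was trained under.
#'
#' @slot kind `"dnn"` or `"logistic"`.
#' @slot params learned parameters (weight/bias matrices, or the logistic
#'   coefficient vector).
#' @slot threshold propensity cutoff in [0, 1]; `NA` until selected.
#' @slot inputDim feature-vector width the model accepts.
#' @slot fingerprint canonical schema + encoding descriptor string.
#' @slot config the [DnnConfig-class] used for training.
#' @slot log per-epoch training trace (data.frame).
#' @export
setClass("DisorderModel",
  representation(
    kind = "character",
    params = "list",
    threshold = "numeric",
    inputDim = "integer",
    fingerprint = "character",
    config = "DnnConfig",
    log = "data.frame"
  )
)

setValidity("DisorderModel", function(object) {
  if (!object@kind %in% c("dnn", "logistic"))
    return("kind must be 'dnn' or 'logistic'")
  th <- object@threshold
  if (length(th) != 1L || (!is.na(th) && (th < 0 || th > 1)))
    return("threshold must be a single value in [0, 1] or NA")
  TRUE
})

#' RfConfig: random-forest grid-search controls for function models
#'
#' @slot nTreesGrid forest sizes to try (default 100/250/500).
#' @slot maxDepthGrid tree depths to try; 0 means unlimited
#'   (default 5/10/unlimited).
#' @slot cvFolds number of cross-validation folds used to score grid
#'   points by mean AUC (default 3).
#' @slot seed integer seed for fold assignment and forest growth.
#' @export
setClass("RfConfig",
  representation(
    nTreesGrid = "integer",
    maxDepthGrid = "integer",
    cvFolds = "integer",
    seed = "integer"
  ),
  prototype(
    nTreesGrid = c(100L, 250L, 500L),
    maxDepthGrid = c(5L, 10L, 0L),
    cvFolds = 3L,
    seed = 1L
  )
)

setValidity("RfConfig", function(object) {
  if (length(object@nTreesGrid) < 1L || length(object@maxDepthGrid) < 1L)
    return("hyper-parameter grids must be non-empty")
  if (any(object@nTreesGrid < 1L)) return("nTreesGrid must be positive")
  if (any(object@maxDepthGrid < 0L)) return("maxDepthGrid must be >= 0")
  if (object@cvFolds < 2L) return("cvFolds must be at least 2")
  TRUE
})

#' FunctionModel: random forest for one disorder function
#'
#' Trained on residues inside putative disordered regions only; its
#' predictions are masked to those regions so function calls can never
#' contradict the disorder prediction.
#'
#' @slot functionLabel one of [functionLabels()].
#' @slot forest fitted `ranger` probability forest.
#' @slot threshold propensity cutoff for the binary call.
#' @slot fingerprint encoding descriptor the model is tied to.
#' @slot gridLog grid-search trace (data.frame of trees/depth/cv AUC).
#' @export
setClass("FunctionModel",
  representation(
    functionLabel = "character",
    forest = "ANY",
    threshold = "numeric",
    fingerprint = "character",
    gridLog = "data.frame"
  )
)

setValidity("FunctionModel", function(object) {
  if (!object@functionLabel %in% functionLabels())
    return("functionLabel must be one of the four disorder functions")
  TRUE
})

#' PredictionResult: aligned disorder and function tracks for one protein
#'
#' @slot proteinId protein identifier.
#' @slot sequence amino-acid sequence (single string).
#' @slot disorderPropensity per-residue disorder propensity in [0, 1].
#' @slot disorderBinary per-residue binary disorder call.
#' @slot functionPropensity L x 4 matrix of function propensities
#'   (columns [functionLabels()]); zero outside predicted disorder.
#' @slot functionBinary L x 4 binary matrix; a residue can only be
#'   function-positive where it is disorder-positive.
#' @export
setClass("PredictionResult",
  representation(
    proteinId = "character",
    sequence = "character",
    disorderPropensity = "numeric",
    disorderBinary = "integer",
    functionPropensity = "matrix",
    functionBinary = "matrix"
  )
)

setValidity("PredictionResult", function(object) {
  L <- nchar(object@sequence)
  if (L < 1L) return("sequence must be non-empty")
  if (length(object@disorderPropensity) != L ||
      length(object@disorderBinary) != L)
    return("disorder tracks must match sequence length")
  if (!identical(dim(object@functionPropensity), c(L, 4L)) ||
      !identical(dim(object@functionBinary), c(L, 4L)))
    return("function tracks must be L x 4")
  if (any(object@disorderPropensity < 0 | object@disorderPropensity > 1))
    return("disorder propensities must lie in [0, 1]")
  if (any(object@functionBinary == 1L & object@disorderBinary == 0L))
    return("function-positive residue with a structured disorder call")
  TRUE
})

#' SimParams: synthetic-dataset generator parameters
#'
#' The generator emulates DisProt-style data: segmental disorder from a
#' two-state Markov chain, an optional fraction of fully disordered
#' chains, profile channels tied to the disorder or function labels with
#' additive per-protein bias and Gaussian noise (clipped to [0, 1]),
#' nuisance channels uniform on [0, 1], and function regions carved as
#' contiguous sub-intervals of disordered segments.
#'
#' @slot nProteins number of proteins to generate.
#' @slot lengthRange integer `c(min, max)` chain length, drawn uniformly.
#' @slot pStayDisorder,pStayOrder Markov stay probabilities; run lengths
#'   are geometric with mean `1/(1 - pStay)`.
#' @slot proteinBiasSd sd of the per-protein offset added to informative
#'   channels (this is what makes protein-level features informative).
#' @slot fullyDisorderedFraction probability a chain is all-disordered.
#' @slot channelEffects named list keyed by target label (`"disorder"` or
#'   a function label); each element a named numeric vector of per-channel
#'   effect sizes.
#' @slot noiseSd sd of the residue-level Gaussian noise.
#' @slot functionCoverage named numeric; probability that a disordered
#'   segment carries each function.
#' @slot seed integer seed.
#' @export
setClass("SimParams",
  representation(
    nProteins = "integer",
    lengthRange = "integer",
    pStayDisorder = "numeric",
    pStayOrder = "numeric",
    proteinBiasSd = "numeric",
    fullyDisorderedFraction = "numeric",
    channelEffects = "list",
    noiseSd = "numeric",
    functionCoverage = "numeric",
    seed = "integer"
  ),
  prototype(
    nProteins = 100L,
    lengthRange = c(50L, 150L),
    pStayDisorder = 0.95,
    pStayOrder = 0.95,
    proteinBiasSd = 0.1,
    fullyDisorderedFraction = 0.05,
    channelEffects = list(),
    noiseSd = 0.1,
    functionCoverage = c(
      protein_binding = 0.5, dna_binding = 0.3,
      rna_binding = 0.3, linker = 0.4
    ),
    seed = 1L
  )
)

setValidity("SimParams", function(object) {
  if (object@nProteins < 1L) return("nProteins must be positive")
  lr <- object@lengthRange
  if (length(lr) != 2L || lr[1L] < 1L || lr[1L] > lr[2L])
    return("lengthRange must be c(min, max) with 1 <= min <= max")
  pr <- c(
    object@pStayDisorder, object@pStayOrder,
    object@fullyDisorderedFraction, object@functionCoverage
  )
  if (any(pr < 0 | pr > 1)) return("probabilities must lie in [0, 1]")
  if (object@proteinBiasSd < 0 || object@noiseSd < 0)
    return("standard deviations must be non-negative")
  tg <- names(object@channelEffects)
  if (length(object@channelEffects) && !all(tg %in% annotationLabels()))
    return("channelEffects must be keyed by annotation labels")
  if (!all(names(object@functionCoverage) %in% functionLabels()))
    return("functionCoverage must be keyed by function labels")
  TRUE
})
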