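#' Accessors for package classes
#'
#' `channels()` returns a schema's ordered channel names, `channelGroups()`
#' the group partition, `profileValues()` the residue x channel matrix,
#' `proteinId()` the protein identifier of an object, and `threshold()` the
#' propensity cutoff of a trained model.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("channelGroups", function(x) standardGeneric("channelGroups"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname accessors
#' @export
setMethod("channels", "ProfileSchema", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("channelGroups", "ProfileSchema", function(x) x@groups)

#' @rdname accessors
#' @export
setMethod("profileValues", "Profile", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("proteinId", "Profile", function(x) x@proteinId)

#' @rdname accessors
#' @export
setMethod("proteinId", "PredictionResult", function(x) x@proteinId)

#' @rdname accessors
#' @export
setMethod("threshold", "DisorderModel", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("threshold", "FunctionModel", function(x) x@threshold)

setMethod("show", "ProfileSchema", function(object) {
  cat(
    "ProfileSchema with", length(object@channels), "channels in",
    length(object@groups), "groups\n"
  )
  for (g in names(object@groups)) {
    cat("  ", g, ": ", length(object@groups[[g]]), " channel(s)\n", sep = "")
  }
})

setMethod("show", "Profile", function(object) {
  cat(
    "Profile for", object@proteinId, "-", nrow(object@values),
    "residues x", ncol(object@values), "channels\n"
  )
})

setMethod("show", "EncodingConfig", function(object) {
  cat(
    "EncodingConfig: residue window", object@residueWindow,
    "| averaging window", object@averageWindow,
    "| protein-level", object@includeProteinLevel, "\n"
  )
  if (length(object@excludedGroups)) {
    cat("  excluded groups:", paste(object@excludedGroups, collapse = ", "), "\n")
  }
  if (length(object@excludedLevels)) {
    cat("  excluded levels:", paste(object@excludedLevels, collapse = ", "), "\n")
  }
})

setMethod("show", "DisorderModel", function(object) {
  cat(
    "DisorderModel (", object@kind, "), input dim ", object@inputDim,
    ", threshold ",
    if (is.na(object@threshold)) "unset" else format(object@threshold, digits = 4),
    "\n",
    sep = ""
  )
})

setMethod("show", "FunctionModel", function(object) {
  cat(
    "FunctionModel for", object@functionLabel, "- threshold",
    format(object@threshold, digits = 4), "\n"
  )
})

setMethod("show", "PredictionResult", function(object) {
  L <- nchar(object@sequence)
  cat(
    "PredictionResult for ", object@proteinId, ": ", L, " residues, ",
    sum(object@disorderBinary), " predicted disordered\n",
    sep = ""
  )
})

setMethod("show", "SimParams", function(object) {
  cat(
    "SimParams:", object@nProteins, "proteins, lengths",
    object@lengthRange[1L], "-", object@lengthRange[2L],
    ", seed", object@seed, "\n"
  )
})
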