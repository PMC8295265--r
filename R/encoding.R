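#' Encoding configurations for the two prediction tasks
#'
#' The disorder task concatenates raw profile values over a 5-residue
#' window, per-channel means over a 15-residue window, and the
#' protein-level summary; the function task uses windows of 1 and 11.
#'
#' @param residueWindow,averageWindow odd window widths.
#' @param includeProteinLevel append the whole-protein summary block.
#' @param excludedGroups schema groups dropped from every level.
#' @param excludedLevels encoding levels dropped entirely.
#' @return An [EncodingConfig-class].
#' @export
EncodingConfig <- function(residueWindow = 5L, averageWindow = 15L,
                           includeProteinLevel = TRUE,
                           excludedGroups = character(0),
                           excludedLevels = character(0)) {
  new("EncodingConfig",
    residueWindow = as.integer(residueWindow),
    averageWindow = as.integer(averageWindow),
    includeProteinLevel = includeProteinLevel,
    excludedGroups = excludedGroups,
    excludedLevels = excludedLevels
  )
}

#' @rdname EncodingConfig
#' @export
disorderEncodingConfig <- function() EncodingConfig(5L, 15L)

#' @rdname EncodingConfig
#' @export
functionEncodingConfig <- function() EncodingConfig(1L, 11L)

activeLevels <- function(config) {
  lv <- setdiff(c("residue", "window", "protein"), config@excludedLevels)
  if (!config@includeProteinLevel) lv <- setdiff(lv, "protein")
  lv
}

activeChannels <- function(config, schema) {
  unknown <- setdiff(config@excludedGroups, names(schema@groups))
  if (length(unknown)) {
    stop("schema has no group(s): ", paste(unknown, collapse = ", "))
  }
  drop <- unlist(schema@groups[config@excludedGroups], use.names = FALSE)
  setdiff(schema@channels, drop)
}

#' Number of features produced by an encoding configuration
#'
#' Closed form: with P retained channels, the residue level contributes
#' `residueWindow * P` columns, the window level `P`, and the protein
#' level `P + 3` (per-channel means, normalised length, two terminus
#' distances). The default disorder configuration over the 45-channel
#' schema gives `5*45 + 45 + 48 = 318`.
#'
#' @param config an [EncodingConfig-class].
#' @param schema a [ProfileSchema-class].
#' @return Integer feature count.
#' @export
featureCount <- function(config, schema) {
  p <- length(activeChannels(config, schema))
  lv <- activeLevels(config)
  n <- 0L
  if ("residue" %in% lv) n <- n + config@residueWindow * p
  if ("window" %in% lv) n <- n + p
  if ("protein" %in% lv) n <- n + p + 3L
  n
}

#' Centred window slice with fill
#'
#' Values at positions `center - w .. center + w` (`w = (width - 1)/2`);
#' positions outside the chain are replaced by `fill`.
#'
#' @param track numeric per-residue vector.
#' @param center 1-based centre position.
#' @param width odd window width.
#' @param fill value used for out-of-range slots.
#' @return Numeric vector of length `width`.
#' @examples
#' windowSlice(1:5, center = 1, width = 5, fill = 0) # 0 0 1 2 3
#' @export
windowSlice <- function(track, center, width, fill) {
  if (width %% 2L == 0L) stop("window width must be odd")
  L <- length(track)
  stopifnot(center >= 1L, center <= L)
  w <- (width - 1L) %/% 2L
  idx <- (center - w):(center + w)
  out <- rep(fill, width)
  ok <- idx >= 1L & idx <= L
  out[ok] <- track[idx[ok]]
  out
}

#' Whole-protein summary features
#'
#' Per-channel means over the chain, a length feature `min(L, 10000) /
#' 10000`, and per-residue distances to the N terminus (`(i - 1)/L`) and
#' C terminus (`(L - i)/L`). The means and length are broadcast to every
#' residue; the two distances vary along the chain.
#'
#' @param profile a [Profile-class] (or plain numeric matrix).
#' @return L x (P + 3) numeric matrix.
#' @export
proteinLevelFeatures <- function(profile) {
  v <- if (methods::is(profile, "Profile")) profile@values else profile
  L <- nrow(v)
  mu <- colMeans(v)
  i <- seq_len(L)
  cbind(
    matrix(mu, nrow = L, ncol = length(mu), byrow = TRUE,
      dimnames = list(NULL, paste0("prot.mean.", colnames(v)))),
    prot.length = rep(min(L, 10000L) / 10000, L),
    prot.ndist = (i - 1) / L,
    prot.cdist = (L - i) / L
  )
}

# mean over a centred window where out-of-range slots take `fill` values
# (a per-channel vector); vectorised over all residues and channels
shiftedMatrix <- function(v, offset, fillRow) {
  L <- nrow(v)
  idx <- seq_len(L) + offset
  out <- matrix(fillRow, nrow = L, ncol = ncol(v), byrow = TRUE)
  ok <- idx >= 1L & idx <= L
  out[ok, ] <- v[idx[ok], , drop = FALSE]
  out
}

#' Encode a profile into per-residue feature vectors
#'
#' Three feature blocks per residue: the residue level concatenates raw
#' channel values over the small centred window; the window level is the
#' per-channel arithmetic mean over the larger centred window; the
#' protein level is [proteinLevelFeatures()]. Window slots that fall
#' outside the chain are filled with the protein-level channel mean, so a
#' profile that is constant in every channel encodes to that constant at
#' every position and level. Column order is residue block
#' (position-major, channel-minor), window block, protein block, with
#' provenance-bearing column names.
#'
#' @param profile a [Profile-class].
#' @param config an [EncodingConfig-class].
#' @param schema the [ProfileSchema-class] the profile conforms to.
#' @return L x F numeric matrix with attributes `proteinId` and
#'   `fingerprint` (the schema/encoding descriptor checked by models).
#' @examples
#' sc <- defaultSchema()
#' m <- matrix(0.5, nrow = 4, ncol = 45,
#'   dimnames = list(NULL, channels(sc)))
#' ncol(encodeProfile(Profile("p", m, sc), disorderEncodingConfig(), sc))
#' @export
encodeProfile <- function(profile, config, schema) {
  keep <- activeChannels(config, schema)
  miss <- setdiff(keep, colnames(profile@values))
  if (length(miss)) {
    stop("profile does not conform to schema; missing: ",
      paste(miss, collapse = ", "))
  }
  v <- profile@values[, keep, drop = FALSE]
  L <- nrow(v)
  if (L < 1L) stop("empty profile")
  mu <- colMeans(v)
  lv <- activeLevels(config)
  blocks <- list()

  if ("residue" %in% lv) {
    w <- (config@residueWindow - 1L) %/% 2L
    res <- lapply((-w):w, function(o) {
      m <- shiftedMatrix(v, o, mu)
      colnames(m) <- paste0(
        "res.", ifelse(o < 0, paste0("m", -o), paste0("p", o)), ".", keep
      )
      m
    })
    blocks <- c(blocks, res)
  }
  if ("window" %in% lv) {
    w <- (config@averageWindow - 1L) %/% 2L
    acc <- matrix(0, nrow = L, ncol = ncol(v))
    for (o in (-w):w) acc <- acc + shiftedMatrix(v, o, mu)
    win <- acc / config@averageWindow
    colnames(win) <- paste0("win.", keep)
    blocks <- c(blocks, list(win))
  }
  if ("protein" %in% lv) {
    blocks <- c(blocks, list(proteinLevelFeatures(v)))
  }
  out <- do.call(cbind, blocks)
  if (!all(is.finite(out))) stop("non-finite feature values produced")
  attr(out, "proteinId") <- profile@proteinId
  attr(out, "fingerprint") <- encodingFingerprint(config, schema)
  out
}

#' Canonical descriptor of a schema + encoding pair
#'
#' A plain-text fingerprint recorded in every trained model and checked
#' at prediction time, so a model can refuse features produced under a
#' different schema or encoding.
#'
#' @inheritParams encodeProfile
#' @return Single character string.
#' @export
encodingFingerprint <- function(config, schema) {
  paste(
    paste(activeChannels(config, schema), collapse = ","),
    config@residueWindow, config@averageWindow,
    paste(sort(activeLevels(config)), collapse = "+"),
    sep = "|"
  )
}

#' Encode a list of profiles into one stacked feature matrix
#'
#' @param profiles list of [Profile-class] objects.
#' @inheritParams encodeProfile
#' @return Row-bound feature matrix with attributes `proteinId` (one id
#'   per row) and `fingerprint`.
#' @export
encodeDataset <- function(profiles, config, schema) {
  mats <- lapply(profiles, encodeProfile, config = config, schema = schema)
  out <- do.call(rbind, mats)
  attr(out, "proteinId") <- rep(
    vapply(profiles, proteinId, character(1)),
    vapply(mats, nrow, integer(1))
  )
  attr(out, "fingerprint") <- encodingFingerprint(config, schema)
  out
}

#' Write a feature matrix as TSV for inspection
#'
#' @param features matrix from [encodeProfile()] or [encodeDataset()].
#' @param path output file.
#' @export
writeFeatureMatrix <- function(features, path) {
  df <- as.data.frame(features)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
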