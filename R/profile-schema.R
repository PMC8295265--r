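AA20 <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Construct a profile schema
#'
#' @param channels ordered character vector of channel names.
#' @param groups named list partitioning the channels into groups.
#' @param ranges optional 2 x P matrix (rows min/max); defaults to [0, 1]
#'   for every channel.
#' @return A [ProfileSchema-class].
#' @export
ProfileSchema <- function(channels, groups, ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- matrix(
      rep(c(0, 1), length(channels)),
      nrow = 2L, dimnames = list(c("min", "max"), channels)
    )
  }
  new("ProfileSchema", channels = channels, ranges = ranges, groups = groups)
}

#' The default 45-channel profile schema
#'
#' The default sequence profile carries, per residue: 20 logistic-squashed
#' PSSM substitution scores; 1 entropy-based conservation score derived
#' from the PSSM; 3 secondary-structure probabilities (helix/strand/coil)
#' plus their 3 binary calls; IUPred long and short disorder propensities
#' plus binaries (4); disorder-function baseline channels — DisoRDPbind
#' protein/DNA/RNA propensities and binaries (6), a MoRF propensity and
#' binary (2), a linker propensity and binary (2); and 4 min-max-scaled
#' physicochemical scalars (hydrophobicity, charge, polarity, volume).
#' Total: 45 channels, each in [0, 1]. With the disorder-task encoder
#' (residue window 5, averaging window 15, protein-level features) this
#' yields the 318-dimensional input of the disorder network
#' (7 * 45 + 3 = 318).
#'
#' @return A [ProfileSchema-class] with 45 channels in 6 groups.
#' @examples
#' sc <- defaultSchema()
#' length(channels(sc)) # 45
#' @export
defaultSchema <- function() {
  groups <- list(
    pssm = paste0("pssm_", AA20),
    conservation = "conservation",
    secondary_structure = c(
      "ss_prob_H", "ss_prob_E", "ss_prob_C",
      "ss_bin_H", "ss_bin_E", "ss_bin_C"
    ),
    iupred = c(
      "iupred_long", "iupred_long_bin",
      "iupred_short", "iupred_short_bin"
    ),
    function_predictors = c(
      "disordpbind_prot", "disordpbind_prot_bin",
      "disordpbind_dna", "disordpbind_dna_bin",
      "disordpbind_rna", "disordpbind_rna_bin",
      "fmorfpred", "fmorfpred_bin",
      "dflpred", "dflpred_bin"
    ),
    physchem = c("hydrophobicity", "charge", "polarity", "volume")
  )
  ProfileSchema(unlist(groups, use.names = FALSE), groups)
}

#' Write / read a schema as a plain text config
#'
#' One line per channel: `name<TAB>group<TAB>min<TAB>max`, so ablation
#' configs can reference groups by name.
#'
#' @param schema a [ProfileSchema-class].
#' @param path file path.
#' @return `readSchema` returns a [ProfileSchema-class];
#'   `writeSchema` returns `path` invisibly.
#' @export
writeSchema <- function(schema, path) {
  grp <- rep(names(schema@groups), lengths(schema@groups))
  names(grp) <- unlist(schema@groups, use.names = FALSE)
  df <- data.frame(
    channel = schema@channels,
    group = grp[schema@channels],
    min = schema@ranges[1L, ],
    max = schema@ranges[2L, ]
  )
  utils::write.table(
    df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeSchema
#' @export
readSchema <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  groups <- split(df$channel, df$group)
  # preserve first-appearance group order
  groups <- groups[unique(df$group)]
  ranges <- rbind(min = df$min, max = df$max)
  colnames(ranges) <- df$channel
  ProfileSchema(df$channel, groups, ranges)
}

#' Construct a per-residue profile
#'
#' @param proteinId protein identifier.
#' @param values L x P numeric matrix with column names; columns are
#'   reordered to the schema if one is supplied.
#' @param schema optional [ProfileSchema-class]; when given, the column
#'   set must match the schema channels and values must respect each
#'   channel's declared range.
#' @return A [Profile-class].
#' @export
Profile <- function(proteinId, values, schema = NULL) {
  if (!is.null(schema)) {
    miss <- setdiff(schema@channels, colnames(values))
    if (length(miss)) {
      stop("profile for '", proteinId, "' is missing channel(s): ",
        paste(miss, collapse = ", "))
    }
    values <- values[, schema@channels, drop = FALSE]
    lo <- schema@ranges[1L, ]
    hi <- schema@ranges[2L, ]
    bad <- which(
      colSums(sweep(values, 2L, lo, "<")) > 0 |
        colSums(sweep(values, 2L, hi, ">")) > 0
    )
    if (length(bad)) {
      stop("profile for '", proteinId, "' has out-of-range values in: ",
        paste(schema@channels[bad], collapse = ", "))
    }
  }
  new("Profile", proteinId = proteinId, values = values)
}

#' Entropy-based conservation from a PSSM row
#'
#' The 20 substitution scores of a residue are softmax-normalised into a
#' probability vector p over the amino-acid alphabet and conservation is
#' reported as `1 - H(p) / ln(20)`, where H is the Shannon entropy in
#' nats. A flat row (uniform p, maximal entropy) scores 0; a row
#' dominated by one letter approaches 1. Adding a constant to all 20
#' scores leaves the value unchanged (softmax shift invariance).
#'
#' @param pssmRow numeric vector of 20 finite substitution scores, or an
#'   L x 20 matrix of rows.
#' @return Conservation score(s) in [0, 1].
#' @examples
#' pssmConservation(rep(0, 20)) # 0
#' @export
pssmConservation <- function(pssmRow) {
  if (is.matrix(pssmRow)) {
    return(apply(pssmRow, 1L, pssmConservation))
  }
  if (length(pssmRow) != 20L || !all(is.finite(pssmRow))) {
    stop("pssmRow must be 20 finite values")
  }
  z <- pssmRow - max(pssmRow)
  p <- exp(z) / sum(exp(z))
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  1 - h / log(20)
}

#' Squash PSSM substitution scores to [0, 1]
#'
#' Elementwise logistic transform `x -> 1 / (1 + exp(-x))`, making raw
#' PSSM integer scores range-compatible with the other profile channels
#' while preserving their order.
#'
#' @param x numeric vector or matrix of finite scores.
#' @return Values in (0, 1), same shape as `x`.
#' @examples
#' scalePssm(0) # 0.5
#' @export
scalePssm <- function(x) {
  if (!all(is.finite(x))) stop("scores must be finite")
  1 / (1 + exp(-x))
}

# Kyte-Doolittle hydrophobicity, net charge at pH 7, Grantham polarity and
# residue volume (A^3), each min-max scaled to [0,1] over the 20 letters.
physchemTable <- function() {
  hydro <- c(
    A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
  )
  charge <- c(
    A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0.1,
    I = 0, K = 1, L = 0, M = 0, N = 0, P = 0, Q = 0,
    R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0
  )
  polar <- c(
    A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0, H = 10.4,
    I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6, P = 8.0, Q = 10.5,
    R = 10.5, S = 9.2, T = 8.6, V = 5.9, W = 5.4, Y = 6.2
  )
  vol <- c(
    A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9, G = 60.1,
    H = 153.2, I = 166.7, K = 168.6, L = 166.7, M = 162.9, N = 114.1,
    P = 112.7, Q = 143.8, R = 173.4, S = 89.0, T = 116.1, V = 140.0,
    W = 227.8, Y = 193.6
  )
  mm <- function(v) (v - min(v)) / (max(v) - min(v))
  tab <- cbind(
    hydrophobicity = mm(hydro), charge = mm(charge),
    polarity = mm(polar), volume = mm(vol)
  )
  # unknown residue: column mid-point
  rbind(tab, X = colMeans(tab))
}

#' Physicochemical channels for a sequence
#'
#' Looks up the four bundled min-max-scaled residue scales
#' (hydrophobicity, charge, polarity, volume) for every position of a
#' sequence; the unknown letter X receives the scale mid-point.
#'
#' @param sequence amino-acid sequence (single string over the 20
#'   standard letters plus X).
#' @return L x 4 numeric matrix.
#' @export
physchemChannels <- function(sequence) {
  tab <- physchemTable()
  aa <- strsplit(sequence, "")[[1L]]
  bad <- setdiff(aa, rownames(tab))
  if (length(bad)) {
    stop("unsupported residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  tab[aa, , drop = FALSE]
}
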