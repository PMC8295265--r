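#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and any letter outside the 20 standard amino
#' acids is mapped to X (real curated sequences contain nonstandard
#' letters; rejecting them would drop whole chains). The record id is the
#' first whitespace-delimited token of the header.
#'
#' @param path FASTA file.
#' @return A [Biostrings::AAStringSet] named by record ids, in file order.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- lines[nzchar(trimws(lines))]
  if (length(nonEmpty) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(nonEmpty[1L], ">")) {
    stop("malformed FASTA (sequence line before any header): ", path)
  }
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(
    strsplit(names(aa), "\\s+"), function(x) x[1L], character(1)
  )
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0L)) {
    stop("zero-length sequence for id ", ids[nchar(seqs) == 0L][1L])
  }
  seqs <- gsub(paste0("[^", paste(AA20, collapse = ""), "]"), "X", seqs)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write protein sequences as FASTA
#'
#' @param proteins named [Biostrings::AAStringSet] or named character
#'   vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(proteins, path) {
  if (!methods::is(proteins, "AAStringSet")) {
    proteins <- Biostrings::AAStringSet(proteins)
  }
  Biostrings::writeXStringSet(proteins, path)
  invisible(path)
}

#' Read / write region annotations
#'
#' The annotation dialect is a 4-column tab-separated table with header
#' `protein_id`, `start`, `end`, `label`; coordinates are 1-based
#' inclusive, labels are drawn from [annotationLabels()].
#'
#' @param path TSV file.
#' @param proteins optional named sequence set; when given, every region
#'   is checked against its protein's length.
#' @return A data.frame with columns protein_id, start, end, label.
#' @export
readRegionAnnotations <- function(path, proteins = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("annotation file missing column(s): ", paste(miss, collapse = ", "))
  }
  df <- df[, need]
  validateRegions(df, proteins)
  df
}

#' @rdname readRegionAnnotations
#' @param regions annotation data.frame as returned by
#'   `readRegionAnnotations`.
#' @export
writeRegionAnnotations <- function(regions, path) {
  utils::write.table(
    regions, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

validateRegions <- function(regions, proteins = NULL) {
  bad <- setdiff(unique(regions$label), annotationLabels())
  if (length(bad)) {
    stop("unknown annotation label(s): ", paste(bad, collapse = ", "))
  }
  if (any(regions$start < 1L) || any(regions$end < regions$start)) {
    i <- which(regions$start < 1L | regions$end < regions$start)[1L]
    stop(
      "invalid interval [", regions$start[i], ", ", regions$end[i],
      "] for protein ", regions$protein_id[i]
    )
  }
  if (!is.null(proteins)) {
    len <- stats::setNames(width2(proteins), names(proteins))
    unknown <- setdiff(unique(regions$protein_id), names(len))
    if (length(unknown)) {
      stop("annotation for unknown protein(s): ",
        paste(unknown, collapse = ", "))
    }
    over <- which(regions$end > len[regions$protein_id])
    if (length(over)) {
      i <- over[1L]
      stop(
        "region [", regions$start[i], ", ", regions$end[i],
        "] exceeds length of protein ", regions$protein_id[i]
      )
    }
  }
  invisible(TRUE)
}

width2 <- function(proteins) {
  if (methods::is(proteins, "XStringSet")) {
    Biostrings::width(proteins)
  } else {
    nchar(proteins)
  }
}

#' Per-residue 0/1 track from region annotations
#'
#' Residues covered by any region of the requested label are marked 1,
#' all others 0 — the default-structured rule used for DisProt-style
#' data, where positions are taken as ordered unless annotated
#' disordered. Overlapping and duplicated regions are unioned.
#'
#' @param regions annotation data.frame (may contain other proteins and
#'   labels; rows are filtered to `proteinId` + `label`).
#' @param label one of [annotationLabels()].
#' @param proteinId protein identifier.
#' @param seqLength protein length in residues.
#' @return Integer vector of length `seqLength` over {0, 1}.
#' @examples
#' r <- data.frame(
#'   protein_id = "p1", start = c(1, 2), end = c(3, 4),
#'   label = "disorder"
#' )
#' regionsToTrack(r, "disorder", "p1", 5) # 1 1 1 1 0
#' @export
regionsToTrack <- function(regions, label, proteinId, seqLength) {
  stopifnot(label %in% annotationLabels(), seqLength >= 1L)
  track <- integer(seqLength)
  sel <- regions$protein_id == proteinId & regions$label == label
  for (i in which(sel)) {
    s <- regions$start[i]
    e <- regions$end[i]
    if (s < 1L || e > seqLength || s > e) {
      stop(
        "region [", s, ", ", e, "] out of bounds for protein ",
        proteinId, " (length ", seqLength, ")"
      )
    }
    track[s:e] <- 1L
  }
  track
}

#' Tracks for every protein in a sequence set
#'
#' @inheritParams regionsToTrack
#' @param proteins named sequence set ([Biostrings::AAStringSet] or named
#'   character vector).
#' @return Named list of integer tracks, one per protein.
#' @export
labelTracks <- function(regions, label, proteins) {
  len <- width2(proteins)
  out <- lapply(seq_along(proteins), function(i) {
    regionsToTrack(regions, label, names(proteins)[i], len[i])
  })
  names(out) <- names(proteins)
  out
}

#' Read a per-residue profile table
#'
#' Tab-separated, one header row of channel names, one data row per
#' residue. All schema channels must be present; extra columns are
#' ignored and columns may appear in any order (they are reordered to the
#' schema).
#'
#' @param path TSV file.
#' @param schema [ProfileSchema-class] the table must conform to.
#' @param proteinId identifier for the returned profile (default: file
#'   base name without extension).
#' @param seqLength optional declared sequence length; a row-count
#'   mismatch is an error.
#' @return A [Profile-class].
#' @export
readProfileTable <- function(path, schema, proteinId = NULL,
                             seqLength = NULL) {
  if (is.null(proteinId)) {
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(schema@channels, names(df))
  if (length(miss)) {
    stop("profile table ", path, " missing channel(s): ",
      paste(miss, collapse = ", "))
  }
  df <- df[, schema@channels, drop = FALSE]
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
      stop(
        "non-numeric value in profile table ", path, " at row ", bad,
        ", column ", names(df)[j]
      )
    }
  }
  m <- as.matrix(df)
  if (!all(is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(
      "non-finite value in profile table ", path, " at row ", idx[1L],
      ", column ", colnames(m)[idx[2L]]
    )
  }
  if (!is.null(seqLength) && nrow(m) != seqLength) {
    stop(
      "profile table ", path, " has ", nrow(m),
      " rows but the sequence has ", seqLength, " residues"
    )
  }
  Profile(proteinId, m, schema)
}

#' @rdname readProfileTable
#' @param profile a [Profile-class] to write.
#' @export
writeProfileTable <- function(profile, path) {
  df <- as.data.frame(profile@values)
  utils::write.table(
    format(df, digits = 17, scientific = FALSE, trim = TRUE),
    path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write / read a prediction CSV
#'
#' One row per residue: 1-based position, amino acid, disorder propensity
#' and binary call, then a propensity/binary pair for each of the four
#' disorder functions. Propensities are printed with 3 decimals.
#'
#' @param result a [PredictionResult-class].
#' @param path output CSV.
#' @return `writePredictionCsv` returns `path` invisibly;
#'   `readPredictionCsv` returns a [PredictionResult-class] (propensities
#'   at the printed 3-decimal precision).
#' @export
writePredictionCsv <- function(result, path) {
  stopifnot(methods::is(result, "PredictionResult"))
  L <- nchar(result@sequence)
  fl <- functionLabels()
  df <- data.frame(
    position = seq_len(L),
    residue = strsplit(result@sequence, "")[[1L]],
    disorder_propensity = sprintf("%.3f", result@disorderPropensity),
    disorder_binary = result@disorderBinary
  )
  for (f in fl) {
    df[[paste0(f, "_propensity")]] <-
      sprintf("%.3f", result@functionPropensity[, f])
    df[[paste0(f, "_binary")]] <- result@functionBinary[, f]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writePredictionCsv
#' @param proteinId identifier for the reconstructed result (default:
#'   file base name).
#' @export
readPredictionCsv <- function(path, proteinId = NULL) {
  if (is.null(proteinId)) {
    proteinId <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fl <- functionLabels()
  fp <- as.matrix(df[, paste0(fl, "_propensity")])
  fb <- as.matrix(df[, paste0(fl, "_binary")])
  colnames(fp) <- colnames(fb) <- fl
  new("PredictionResult",
    proteinId = proteinId,
    sequence = paste(df$residue, collapse = ""),
    disorderPropensity = df$disorder_propensity,
    disorderBinary = as.integer(df$disorder_binary),
    functionPropensity = fp,
    functionBinary = matrix(as.integer(fb), ncol = 4L,
      dimnames = list(NULL, fl))
  )
}
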