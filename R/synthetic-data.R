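#' Construct synthetic-dataset parameters
#'
#' @param nProteins number of proteins.
#' @param lengthRange integer `c(min, max)` chain length.
#' @param pStayDisorder,pStayOrder Markov stay probabilities for the
#'   disorder segment process.
#' @param proteinBiasSd sd of the per-protein offset added to
#'   informative channels.
#' @param fullyDisorderedFraction probability a protein is generated
#'   all-disordered.
#' @param channelEffects named list keyed by target label; each element
#'   a named numeric vector of channel effect sizes.
#' @param noiseSd residue-level Gaussian noise sd.
#' @param functionCoverage per-function probability that a disordered
#'   segment carries the function.
#' @param seed integer seed.
#' @return A [SimParams-class].
#' @export
SimParams <- function(nProteins = 100L, lengthRange = c(50L, 150L),
                      pStayDisorder = 0.95, pStayOrder = 0.95,
                      proteinBiasSd = 0.1,
                      fullyDisorderedFraction = 0.05,
                      channelEffects = list(),
                      noiseSd = 0.1,
                      functionCoverage = c(
                        protein_binding = 0.5, dna_binding = 0.3,
                        rna_binding = 0.3, linker = 0.4
                      ),
                      seed = 1L) {
  new("SimParams",
    nProteins = as.integer(nProteins),
    lengthRange = as.integer(lengthRange),
    pStayDisorder = pStayDisorder, pStayOrder = pStayOrder,
    proteinBiasSd = proteinBiasSd,
    fullyDisorderedFraction = fullyDisorderedFraction,
    channelEffects = channelEffects,
    noiseSd = noiseSd,
    functionCoverage = functionCoverage,
    seed = as.integer(seed)
  )
}

clip01 <- function(x) pmin(1, pmax(0, x))

# two-state disorder chain; initial state from the stationary law
markovTrack <- function(L, pStayD, pStayO) {
  leaveD <- 1 - pStayD
  leaveO <- 1 - pStayO
  statD <- if (leaveD + leaveO == 0) 0.5 else leaveO / (leaveD + leaveO)
  s <- integer(L)
  s[1L] <- stats::rbinom(1L, 1L, statD)
  if (L > 1L) {
    u <- stats::runif(L - 1L)
    for (i in 2L:L) {
      stay <- if (s[i - 1L] == 1L) pStayD else pStayO
      s[i] <- if (u[i - 1L] < stay) s[i - 1L] else 1L - s[i - 1L]
    }
  }
  s
}

runsOf <- function(track, value = 1L) {
  r <- rle(track)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == value
  cbind(start = starts[keep], end = ends[keep])
}

#' Generate a synthetic disorder dataset
#'
#' Emulates the statistical structure of DisProt-style training data:
#' chains of uniform random length whose disorder track follows a
#' two-state Markov chain (geometric segment lengths), with a
#' configurable fraction of chains generated fully disordered; profile
#' channels listed in `channelEffects` take the value
#' `clip01(effect * label + bias + noise)` where the bias is a
#' per-protein Normal(0, proteinBiasSd) draw shared by all informative
#' channels (making whole-chain averages genuinely informative) and the
#' noise is residue-level Normal(0, noiseSd); all other channels are
#' iid Uniform(0, 1). Function regions are carved as contiguous random
#' sub-intervals of disordered segments with the configured per-function
#' coverage probability, so function annotations never extend outside
#' disorder. Sequences are uniform over the 20 standard letters. Fully
#' reproducible from the seed.
#'
#' @param params a [SimParams-class].
#' @param schema a [ProfileSchema-class] (effect-map keys must be schema
#'   channels).
#' @return List with `proteins` ([Biostrings::AAStringSet]),
#'   `profiles` (named list of [Profile-class]), `annotations`
#'   (data.frame) and `params`.
#' @export
simulateDataset <- function(params, schema = defaultSchema()) {
  effCh <- unique(unlist(lapply(params@channelEffects, names)))
  bad <- setdiff(effCh, schema@channels)
  if (length(bad)) {
    stop("effect map references unknown channel(s): ",
      paste(bad, collapse = ", "))
  }
  set.seed(params@seed)
  P <- length(schema@channels)
  ids <- sprintf("sim%04d", seq_len(params@nProteins))
  seqs <- character(params@nProteins)
  profiles <- vector("list", params@nProteins)
  ann <- list()

  for (i in seq_len(params@nProteins)) {
    # sample() treats a scalar as 1:n; guard the degenerate range
    lr <- params@lengthRange
    L <- if (lr[1L] == lr[2L]) lr[1L] else sample(lr[1L]:lr[2L], 1L)
    seqs[i] <- paste(sample(AA20, L, replace = TRUE), collapse = "")
    full <- stats::runif(1L) < params@fullyDisorderedFraction
    dis <- if (full) {
      rep(1L, L)
    } else {
      markovTrack(L, params@pStayDisorder, params@pStayOrder)
    }
    segs <- runsOf(dis)
    if (nrow(segs)) {
      ann[[length(ann) + 1L]] <- data.frame(
        protein_id = ids[i], start = segs[, "start"],
        end = segs[, "end"], label = "disorder"
      )
    }
    # function sub-intervals of disordered segments
    funTracks <- list()
    for (f in names(params@functionCoverage)) {
      tr <- integer(L)
      for (s in seq_len(nrow(segs))) {
        if (stats::runif(1L) >= params@functionCoverage[[f]]) next
        a <- segs[s, "start"]
        b <- segs[s, "end"]
        len <- sample(seq_len(b - a + 1L), 1L)
        st <- a + sample.int(b - a + 2L - len, 1L) - 1L
        tr[st:(st + len - 1L)] <- 1L
        ann[[length(ann) + 1L]] <- data.frame(
          protein_id = ids[i], start = st, end = st + len - 1L, label = f
        )
      }
      funTracks[[f]] <- tr
    }
    bias <- stats::rnorm(1L, 0, params@proteinBiasSd)
    vals <- matrix(stats::runif(L * P), nrow = L,
      dimnames = list(NULL, schema@channels))
    for (target in names(params@channelEffects)) {
      lab <- if (target == "disorder") dis else funTracks[[target]]
      eff <- params@channelEffects[[target]]
      for (ch in names(eff)) {
        vals[, ch] <- clip01(
          eff[[ch]] * lab + bias + stats::rnorm(L, 0, params@noiseSd)
        )
      }
    }
    profiles[[i]] <- Profile(ids[i], vals, schema)
  }
  proteins <- Biostrings::AAStringSet(seqs)
  names(proteins) <- ids
  names(profiles) <- ids
  annotations <- if (length(ann)) {
    do.call(rbind, ann)
  } else {
    data.frame(
      protein_id = character(0), start = integer(0),
      end = integer(0), label = character(0)
    )
  }
  list(
    proteins = proteins, profiles = profiles,
    annotations = annotations, params = params
  )
}

#' Write a simulated dataset to a directory
#'
#' Emits the on-disk dialects consumed by the readers: a FASTA of
#' sequences, one profile TSV per protein under `profiles/`, the region
#' annotation TSV, the schema config, and a JSON sidecar recording the
#' generator parameters and seed.
#'
#' @param dataset list from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @param schema the schema the profiles conform to.
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(dataset, dir, schema = defaultSchema()) {
  dir.create(file.path(dir, "profiles"), recursive = TRUE,
    showWarnings = FALSE)
  writeProteinFasta(dataset$proteins, file.path(dir, "sequences.fasta"))
  for (id in names(dataset$profiles)) {
    writeProfileTable(
      dataset$profiles[[id]],
      file.path(dir, "profiles", paste0(id, ".tsv"))
    )
  }
  writeRegionAnnotations(
    dataset$annotations, file.path(dir, "annotations.tsv")
  )
  writeSchema(schema, file.path(dir, "schema.tsv"))
  p <- dataset$params
  jsonlite::write_json(
    list(
      nProteins = p@nProteins, lengthRange = p@lengthRange,
      pStayDisorder = p@pStayDisorder, pStayOrder = p@pStayOrder,
      proteinBiasSd = p@proteinBiasSd,
      fullyDisorderedFraction = p@fullyDisorderedFraction,
      channelEffects = p@channelEffects, noiseSd = p@noiseSd,
      functionCoverage = as.list(p@functionCoverage), seed = p@seed
    ),
    file.path(dir, "params.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a dataset directory written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param schema optional schema; defaults to the bundled `schema.tsv`.
#' @return List with `proteins`, `profiles`, `annotations`, `schema`.
#' @export
readDataset <- function(dir, schema = NULL) {
  if (is.null(schema)) {
    sp <- file.path(dir, "schema.tsv")
    schema <- if (file.exists(sp)) readSchema(sp) else defaultSchema()
  }
  proteins <- readProteinFasta(file.path(dir, "sequences.fasta"))
  profiles <- lapply(names(proteins), function(id) {
    readProfileTable(
      file.path(dir, "profiles", paste0(id, ".tsv")),
      schema,
      proteinId = id,
      seqLength = Biostrings::width(proteins)[match(id, names(proteins))]
    )
  })
  names(profiles) <- names(proteins)
  annPath <- file.path(dir, "annotations.tsv")
  annotations <- if (file.exists(annPath)) {
    readRegionAnnotations(annPath, proteins)
  } else {
    NULL
  }
  list(
    proteins = proteins, profiles = profiles,
    annotations = annotations, schema = schema
  )
}

#' Named fixture datasets used across the test surface
#'
#' Four deterministic datasets generated from one seed:
#' \describe{
#'   \item{separable}{strong single-channel disorder signal
#'     (effect 1.0 on `iupred_long`, noise sd 0.1, bias sd 0.05); 200
#'     proteins. Supports held-out disorder AUC well above 0.95.}
#'   \item{null}{no channel carries any signal; 100 proteins. Trained
#'     models hover at AUC 0.5.}
#'   \item{protein_level_signal}{bias-dominated: the main disorder
#'     signal (effect 0.5 on `ss_prob_C`) is buried in heavy
#'     residue-level noise (sd 0.35) on top of a per-protein bias
#'     (sd 0.2), so individual residue values are weak while the
#'     whole-chain channel mean cleanly reveals each protein's bias and
#'     overall disorder load; small side-effects (0.25) on one channel
#'     each of the PSSM, IUPred and function-predictor groups keep the
#'     other input families informative; 150 proteins.}
#'   \item{function_toy}{disorder signal on `iupred_long` plus one
#'     dedicated channel per disorder function (DisoRDPbind
#'     protein/DNA/RNA and the linker channel); 150 proteins.}
#' }
#'
#' @param seed integer seed (sub-seeds are derived per fixture).
#' @param schema a [ProfileSchema-class].
#' @return Named list of datasets as returned by [simulateDataset()].
#' @export
fixtureSuite <- function(seed = 1L, schema = defaultSchema()) {
  list(
    separable = simulateDataset(SimParams(
      nProteins = 200L, lengthRange = c(50L, 120L),
      proteinBiasSd = 0.05, fullyDisorderedFraction = 0.05,
      channelEffects = list(disorder = c(iupred_long = 1.0)),
      noiseSd = 0.1, seed = seed
    ), schema),
    null = simulateDataset(SimParams(
      nProteins = 100L, lengthRange = c(50L, 120L),
      proteinBiasSd = 0.05, fullyDisorderedFraction = 0.05,
      channelEffects = list(), noiseSd = 0.1, seed = seed + 1L
    ), schema),
    protein_level_signal = simulateDataset(SimParams(
      nProteins = 150L, lengthRange = c(40L, 100L),
      proteinBiasSd = 0.2, fullyDisorderedFraction = 0.05,
      channelEffects = list(disorder = c(
        ss_prob_C = 0.5, iupred_long = 0.25, pssm_A = 0.25,
        disordpbind_prot = 0.25
      )),
      noiseSd = 0.35, seed = seed + 2L
    ), schema),
    function_toy = simulateDataset(SimParams(
      nProteins = 150L, lengthRange = c(50L, 120L),
      proteinBiasSd = 0.05, fullyDisorderedFraction = 0.05,
      channelEffects = list(
        disorder = c(iupred_long = 1.0),
        protein_binding = c(disordpbind_prot = 0.8),
        dna_binding = c(disordpbind_dna = 0.8),
        rna_binding = c(disordpbind_rna = 0.8),
        linker = c(dflpred = 0.8)
      ),
      noiseSd = 0.1, seed = seed + 3L
    ), schema)
  )
}

#' Split a dataset into train/validation/test partitions by protein
#'
#' @param dataset list from [simulateDataset()].
#' @param fractions numeric of 3 summing to 1 (default 0.6/0.2/0.2).
#' @param seed integer seed for the shuffle.
#' @return List of three datasets with the same structure.
#' @export
splitDataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  ids <- names(dataset$profiles)
  set.seed(seed)
  ids <- sample(ids)
  n <- length(ids)
  nTr <- max(1L, round(fractions[1L] * n))
  nVa <- max(1L, round(fractions[2L] * n))
  parts <- list(
    train = ids[seq_len(nTr)],
    validation = ids[(nTr + 1L):(nTr + nVa)],
    test = ids[(nTr + nVa + 1L):n]
  )
  lapply(parts, function(sel) {
    list(
      proteins = dataset$proteins[sel],
      profiles = dataset$profiles[sel],
      annotations = dataset$annotations[
        dataset$annotations$protein_id %in% sel, , drop = FALSE
      ],
      params = dataset$params
    )
  })
}
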