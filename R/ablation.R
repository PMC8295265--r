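#' The six ablation configurations
#'
#' Each configuration removes exactly one component of the full
#' disorder-task encoding: the disorder-function channels of the
#' profile (`no_function_profile`), one of the three encoding levels
#' (`no_protein_level`, `no_window_level`, `no_residue_level`), the 20
#' PSSM channels (`no_pssm`), or the IUPred channels (`no_iupred`).
#' Group removals drop the group's channels from all levels; level
#' removals drop that feature block entirely.
#'
#' @param schema a [ProfileSchema-class]; must contain the named groups.
#' @param base the full-model [EncodingConfig-class].
#' @return Named list of six [EncodingConfig-class] objects.
#' @export
makeAblationConfigs <- function(schema = defaultSchema(),
                                base = disorderEncodingConfig()) {
  need <- c("function_predictors", "pssm", "iupred")
  miss <- setdiff(need, names(schema@groups))
  if (length(miss)) {
    stop("schema lacks ablation group(s): ", paste(miss, collapse = ", "))
  }
  modify <- function(groups = character(0), levels = character(0)) {
    EncodingConfig(
      residueWindow = base@residueWindow,
      averageWindow = base@averageWindow,
      includeProteinLevel = base@includeProteinLevel,
      excludedGroups = union(base@excludedGroups, groups),
      excludedLevels = union(base@excludedLevels, levels)
    )
  }
  list(
    no_function_profile = modify(groups = "function_predictors"),
    no_protein_level = modify(levels = "protein"),
    no_window_level = modify(levels = "window"),
    no_residue_level = modify(levels = "residue"),
    no_pssm = modify(groups = "pssm"),
    no_iupred = modify(groups = "iupred")
  )
}

#' Train and evaluate the disorder model under each ablation
#'
#' Trains the full model and the six single-component ablations under
#' the same seed regime on the training split, selects thresholds on
#' the validation split, evaluates all seven on the test split
#' (dataset-level AUC/MCC/F1), and tests each ablation against the
#' full model with the paired half-dataset resampling procedure on AUC.
#'
#' @param splits list with `train`, `validation`, `test` datasets
#'   (disjoint by protein).
#' @param schema a [ProfileSchema-class].
#' @param dnnConfig base [DnnConfig-class] reused for every
#'   configuration.
#' @param seed integer seed for the resampling comparisons.
#' @return data.frame with one row per configuration (the full model
#'   first, named `fldpnn_full`): name, nFeatures, auc, mcc, f1, and
#'   the resampling p-value vs the full model (NA for the full row).
#' @export
runAblation <- function(splits, schema = defaultSchema(),
                        dnnConfig = DnnConfig(), seed = 1L) {
  base <- disorderEncodingConfig()
  configs <- c(
    list(fldpnn_full = base),
    makeAblationConfigs(schema, base)
  )
  testTracks <- disorderTracks(splits$test)
  rows <- list()
  propTracks <- list()
  for (nm in names(configs)) {
    cf <- configs[[nm]]
    tr <- datasetXY(splits$train, cf, schema)
    va <- datasetXY(splits$validation, cf, schema)
    model <- trainDisorderModel(tr$X, tr$y, va$X, va$y, dnnConfig)
    teX <- encodeDataset(splits$test$profiles, cf, schema)
    prop <- predictPropensity(model, teX)
    bin <- binarize(prop, model@threshold)
    ids <- attr(teX, "proteinId")
    propTracks[[nm]] <- split(prop, factor(ids, levels = unique(ids)))
    y <- unlist(testTracks[names(splits$test$profiles)], use.names = FALSE)
    ev <- evaluatePredictor(y, prop, bin)
    rows[[nm]] <- data.frame(
      name = nm, nFeatures = ncol(teX),
      auc = ev$auc, mcc = ev$mcc, f1 = ev$f1
    )
  }
  out <- do.call(rbind, rows)
  out$pAucVsFull <- NA_real_
  labs <- testTracks[names(splits$test$profiles)]
  for (nm in setdiff(names(configs), "fldpnn_full")) {
    rs <- resamplingSignificance(
      labs, propTracks$fldpnn_full, propTracks[[nm]],
      metric = "AUC", seed = seed
    )
    out$pAucVsFull[out$name == nm] <- rs$pValue
  }
  rownames(out) <- NULL
  out
}

#' Write an ablation results table
#'
#' @param table data.frame from [runAblation()].
#' @param path output path; `.tsv` and `.json` forms are both written.
#' @export
writeAblationTable <- function(table, path) {
  utils::write.table(
    table, paste0(path, ".tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    table, paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(path)
}
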