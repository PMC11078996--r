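## End-to-end pipeline: phantom dataset -> (optional) segmentation ->
## morphometry -> feature table -> patient split -> classifier ->
## evaluation, subgroup analysis and global attribution.  Stages
## communicate through documented on-disk formats only, so real label
## images and metadata tables can replace phantom outputs stage by stage.

#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds derive from it.
#' @param nPatients number of phantom patients.
#' @param useTruthMasks if TRUE features are measured from the generated
#'   ground-truth label images (segmentation stage skipped); if FALSE
#'   intensity images are rendered, segmented with [segmentBaseline()]
#'   and features measured from the predicted labels, with a
#'   segmentation IoU report against truth.
#' @param segEvalImages number of images for the segmentation IoU report.
#' @param dropGroups feature groups to drop before training.
#' @param modelParams overrides for [trainClassifier()] parameters.
#' @param subgroups run the age-bin subgroup analysis.
#' @param topK waterfall size in the summary.
#' @return a named list understood by [runPipeline()].
#' @export
pipelineConfig <- function(seed = 1L, nPatients = 60L, useTruthMasks = TRUE,
                           segEvalImages = 5L, dropGroups = character(),
                           modelParams = list(), subgroups = TRUE,
                           topK = 10L) {
  list(seed = as.integer(seed), nPatients = as.integer(nPatients),
       useTruthMasks = isTRUE(useTruthMasks),
       segEvalImages = as.integer(segEvalImages),
       dropGroups = dropGroups, modelParams = modelParams,
       subgroups = isTRUE(subgroups), topK = as.integer(topK))
}

writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}

#' Run the full oocyte assessment pipeline
#'
#' Executes phantom generation, optional baseline segmentation with IoU
#' evaluation, morphometry, feature assembly, patient-level splitting,
#' classifier training, test-set evaluation, optional subgroup analysis
#' and the mean-absolute-Shapley ranking.  All artefacts (config, feature
#' table, predictions, evaluation and a machine-readable summary) are
#' written into \code{outDir}; a run is reproducible from its stored
#' configuration alone, and repeated runs with the same config produce
#' byte-identical summaries.
#'
#' @param config list from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("oomorph_run_")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeJson(config, file.path(outDir, "config.json"))
  seed <- config$seed

  study <- generateCohortDataset(config$nPatients, seed = seed,
                                 keepLabels = !config$useTruthMasks)
  oo <- oocyteData(study)

  segSummary <- NULL
  if (!config$useTruthMasks) {
    ## segment rendered intensity images and re-measure from predictions
    pairs <- list()
    meas <- vector("list", nrow(oo))
    for (i in seq_len(nrow(oo))) {
      img <- withSeed((as.numeric(seed) + i) %% 2147483647,
                      renderIntensity(study@labels[[i]], study@spec))
      pred <- segmentBaseline(img)
      meas[[i]] <- measureOocyte(pred)
      if (i <= config$segEvalImages)
        pairs[[i]] <- list(label = study@labels[[i]], pred = pred)
    }
    rep <- evaluateSegmentation(pairs)
    segSummary <- rep@summary
    geomCols <- colnames(meas[[1]])
    oo[geomCols] <- do.call(rbind, meas)
  }

  fs <- assembleFeatureTable(oo)
  if (length(config$dropGroups)) fs <- dropFeatureGroups(fs, config$dropGroups)
  utils::write.csv(cbind(sampleInfo(fs), fs@features),
                   file.path(outDir, "features.csv"), row.names = FALSE)
  writeJson(fs@schema, file.path(outDir, "schema.json"))

  split <- patientSplit(sampleInfo(fs)$patient_id, seed = seed)
  model <- trainClassifier(fs, split, params = config$modelParams, seed = seed)

  te <- splitIdx(split, "test")
  pred <- predict(model, fs[te])
  predOut <- cbind(sampleInfo(fs)[te, c("oocyte_id", "patient_id", "clinic")],
                   pred, outcome = outcomeLabels(fs)[te])
  utils::write.csv(predOut, file.path(outDir, "predictions.csv"),
                   row.names = FALSE)

  rep <- evalReport(pred$probability, outcomeLabels(fs)[te])
  evaluation <- list(auc = rep@auc, sensitivity = rep@sensitivity,
                     specificity = rep@specificity, n = rep@n)

  sub <- NULL
  if (config$subgroups) {
    meta <- cbind(sampleInfo(fs)[te, ], oocyte_age = fs@features$oocyte_age[te])
    sub <- subgroupEval(pred$probability, outcomeLabels(fs)[te], meta,
                        by = "age", seed = seed)
    utils::write.csv(sub, file.path(outDir, "subgroups.csv"), row.names = FALSE)
  }

  tr <- splitIdx(split, "train")
  masv <- masvRanking(model, featureMatrix(fs)[te, , drop = FALSE],
                      referenceSet = featureMatrix(fs)[tr, , drop = FALSE],
                      maxReference = 100L, seed = seed)
  utils::write.csv(masv, file.path(outDir, "masv.csv"), row.names = FALSE)

  summary <- list(
    config = config,
    n_oocytes = nrow(oo),
    n_patients = length(unique(oo$patient_id)),
    prevalence = mean(oo$outcome),
    segmentation = segSummary,
    evaluation = evaluation,
    masv_top10 = utils::head(masv, 10))
  writeJson(summary, file.path(outDir, "summary.json"))
  invisible(summary)
}
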