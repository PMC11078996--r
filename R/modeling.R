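## Patient-level splitting, gradient-boosted classification and
## probability ensembling.

#' Patient-level train/validation/test split
#'
#' Splitting is performed at the patient level so no patient contributes
#' oocytes to more than one partition (preventing leakage of
#' patient-specific morphology and outcome base rates).  Patients are
#' assigned by a largest-deficit greedy rule — patients in decreasing
#' order of oocyte count, each placed into the partition currently
#' furthest below its oocyte-level target, seeded random tie-breaking —
#' which keeps realized oocyte fractions within about two percentage
#' points of the request even for heavy-tailed cohort sizes.
#'
#' @param patientIds character vector, one entry per oocyte.
#' @param fractions named numeric(3) summing to 1 (train, validation,
#'   test).
#' @param seed integer seed; the assignment is deterministic given the
#'   seed.
#' @return a [SplitAssignment-class].
#' @export
patientSplit <- function(patientIds,
                         fractions = c(train = 0.6, validation = 0.2, test = 0.2),
                         seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(names(fractions)))
    names(fractions) <- c("train", "validation", "test")
  patientIds <- as.character(patientIds)
  sizes <- table(patientIds)
  total <- length(patientIds)
  if (max(sizes) > max(fractions) * total)
    stop("infeasible split: one patient holds more oocytes than the largest partition")
  arms <- names(fractions)
  withSeed(seed, {
    ord <- names(sizes)[order(-as.vector(sizes), runif(length(sizes)))]
    assigned <- stats::setNames(numeric(length(arms)), arms)
    pat2arm <- character(0)
    for (p in ord) {
      deficit <- fractions * total - assigned
      pick <- arms[order(-deficit, runif(length(arms)))][1]
      pat2arm[p] <- pick
      assigned[pick] <- assigned[pick] + sizes[[p]]
    }
    new("SplitAssignment", split = unname(pat2arm[patientIds]),
        patientId = patientIds, fractions = fractions,
        seed = as.integer(seed))
  })
}

#' @describeIn SplitAssignment-class compact display
#' @param object a SplitAssignment
#' @export
setMethod("show", "SplitAssignment", function(object) {
  tab <- table(factor(object@split, c("train", "validation", "test")))
  cat("SplitAssignment:",
      paste(sprintf("%s=%d (%.1f%%)", names(tab), tab,
                    100 * tab / length(object@split)), collapse = ", "), "\n")
})

#' Row indices of one partition
#' @param split a [SplitAssignment-class]
#' @param which one of \code{"train"}, \code{"validation"}, \code{"test"}
#' @return integer row indices
#' @export
splitIdx <- function(split, which = c("train", "validation", "test")) {
  which <- match.arg(which)
  which(split@split == which)
}

defaultBoostParams <- function() {
  list(objective = "binary:logistic", eval_metric = "auc",
       eta = 0.05, max_depth = 4, min_child_weight = 5,
       subsample = 0.8, colsample_bytree = 1.0,
       nthread = 1, base_score = 0.5)
}

#' Train the gradient-boosted outcome classifier
#'
#' Fits an xgboost gradient-boosted decision-tree ensemble on the
#' training partition, with early stopping on validation AUC.  The
#' hyperparameter defaults (learning rate 0.05, depth 4, minimum child
#' weight 5, row subsampling 0.8, up to 400 rounds, patience 30) are the
#' package's own desk-scale configuration.  Optional per-clinic minority
#' oversampling duplicates minority-class training rows (seeded) until
#' classes balance within each clinic.
#'
#' @param fs an [OocyteFeatureSet-class].
#' @param split a [SplitAssignment-class] aligned with \code{fs}.
#' @param params list of xgboost parameters overriding the defaults.
#' @param nrounds maximum boosting rounds.
#' @param earlyStoppingRounds patience; set \code{NULL} to disable.
#' @param oversampleMinority logical, per-clinic minority duplication.
#' @param seed integer seed (xgboost subsampling and oversampling).
#' @return a [ClassifierModel-class].
#' @export
trainClassifier <- function(fs, split, params = list(), nrounds = 400L,
                            earlyStoppingRounds = 30L,
                            oversampleMinority = FALSE, seed = 1L) {
  stopifnot(is(fs, "OocyteFeatureSet"), is(split, "SplitAssignment"))
  if (length(split@split) != nrow(fs@features))
    stop("split and feature set are not aligned")
  X <- featureMatrix(fs)
  y <- outcomeLabels(fs)
  tr <- splitIdx(split, "train"); va <- splitIdx(split, "validation")
  if (length(intersect(fs@meta$patient_id[tr], fs@meta$patient_id[va])))
    stop("train and validation share patients")
  if (length(unique(y[tr])) < 2)
    stop("training outcome is single-class; cannot fit a classifier")
  trIdx <- tr
  if (oversampleMinority) {
    extra <- integer(0)
    withSeed(seed, for (cl in unique(fs@meta$clinic[tr])) {
      idx <- tr[fs@meta$clinic[tr] == cl]
      tab <- table(factor(y[idx], 0:1))
      if (min(tab) == 0 || diff(range(tab)) == 0) next
      minor <- as.integer(names(which.min(tab)))
      pool <- idx[y[idx] == minor]
      extra <- c(extra, sample(pool, max(tab) - min(tab), replace = TRUE))
    })
    trIdx <- c(tr, extra)
  }
  p <- utils::modifyList(defaultBoostParams(), params)
  p$seed <- as.integer(seed)
  dtrain <- xgboost::xgb.DMatrix(X[trIdx, , drop = FALSE], label = y[trIdx])
  evals <- list(train = dtrain)
  if (length(va)) {
    dval <- xgboost::xgb.DMatrix(X[va, , drop = FALSE], label = y[va])
    evals <- list(train = dtrain, validation = dval)
  }
  booster <- xgboost::xgb.train(params = p, data = dtrain,
                                nrounds = nrounds, evals = evals,
                                early_stopping_rounds =
                                  if (length(va)) earlyStoppingRounds else NULL,
                                verbose = 0)
  best <- suppressWarnings(as.integer(xgboost::xgb.attr(booster, "best_iteration")))
  new("ClassifierModel", booster = booster, featureNames = colnames(X),
      params = p,
      bestIteration = if (length(best) && !is.na(best)) best else NA_integer_,
      nTrainPos = sum(y[trIdx] == 1L), nTrainNeg = sum(y[trIdx] == 0L))
}

#' @describeIn ClassifierModel-class compact display
#' @param object a ClassifierModel
#' @export
setMethod("show", "ClassifierModel", function(object) {
  cat("ClassifierModel:", length(object@featureNames), "features,",
      "trained on", object@nTrainPos, "positive /", object@nTrainNeg,
      "negative oocytes\n")
  if (!is.na(object@bestIteration))
    cat("  early-stopped best iteration:", object@bestIteration, "\n")
})

classifierMatrix <- function(model, newdata) {
  if (is(newdata, "OocyteFeatureSet")) newdata <- featureMatrix(newdata)
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  missing <- setdiff(model@featureNames, colnames(newdata))
  extra <- setdiff(colnames(newdata), model@featureNames)
  if (length(missing) || length(extra))
    stop("feature schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  newdata[, model@featureNames, drop = FALSE]
}

#' Predict outcome probability, logit and label
#'
#' The probability is \code{plogis(logit)} to machine precision and the
#' predicted label is positive exactly when the logit is positive
#' (probability strictly above the 0.5 threshold).
#'
#' @param object a [ClassifierModel-class].
#' @param newdata matrix, data.frame or [OocyteFeatureSet-class] with the
#'   training columns (a schema mismatch raises an error naming the
#'   missing/extra columns).
#' @param ... unused.
#' @return data.frame with columns \code{probability}, \code{logit},
#'   \code{label}.
#' @export
setMethod("predict", "ClassifierModel", function(object, newdata, ...) {
  X <- classifierMatrix(object, newdata)
  logit <- predict(object@booster, xgboost::xgb.DMatrix(X), outputmargin = TRUE)
  data.frame(probability = plogis(logit), logit = logit,
             label = as.integer(logit > 0))
})

#' Combine two probability vectors into an ensemble score
#'
#' Default combination is the unweighted arithmetic mean of the two
#' probabilities; weights are configurable.  The combined score is
#' monotone: if both components for sample i exceed those for sample j,
#' so does the ensemble.
#'
#' @param pA,pB numeric probability vectors in [0, 1], equal length.
#' @param weights numeric(2) non-negative weights (normalised
#'   internally).
#' @return numeric vector of combined probabilities.
#' @export
ensembleProbabilities <- function(pA, pB, weights = c(0.5, 0.5)) {
  if (length(pA) != length(pB)) stop("probability vectors differ in length")
  if (any(pA < 0 | pA > 1 | pB < 0 | pB > 1))
    stop("probabilities must lie in [0, 1]")
  if (length(weights) != 2 || any(weights < 0) || sum(weights) == 0)
    stop("weights must be two non-negative numbers")
  w <- weights / sum(weights)
  w[1] * pA + w[2] * pB
}
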