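## Shapley-value explanation of classifier predictions.
##
## Attributions are computed in logit space with the interventional
## (marginal-expectation) value function over an explicit reference set:
## v(S) is the mean model logit when features in S come from the
## explained sample and the rest from a reference sample.  For tree
## ensembles this is computed exactly (see src/treeshap.cpp), so local
## accuracy holds to floating-point precision: the prior expectation
## (mean model logit over the reference set) plus the sum of per-feature
## attributions equals the sample's logit f(x), and the prediction
## probability is sigmoid(f(x)).

## Flatten an xgboost booster into per-leaf box constraints.
## Returns leaf values, constraint offsets and per-constraint
## (feature, lo, hi) arrays, plus the constant margin offset (the
## booster's global bias) calibrated in double precision.
parseBoosterLeaves <- function(model, calibrationRow) {
  tt <- as.data.frame(xgboost::xgb.model.dt.tree(model = model@booster))
  ## with early stopping, booster predictions use trees 0..best_iteration
  ## (inclusive); restrict the parse to the same set
  best <- suppressWarnings(as.integer(xgboost::xgb.attr(model@booster,
                                                        "best_iteration")))
  if (length(best) == 1L && !is.na(best))
    tt <- tt[tt$Tree <= best, , drop = FALSE]
  leafValue <- numeric(0)
  consFeat <- integer(0); consLo <- numeric(0); consHi <- numeric(0)
  consStart <- 0L
  nF <- length(model@featureNames)
  for (tr in unique(tt$Tree)) {
    sub <- tt[tt$Tree == tr, , drop = FALSE]
    rowByNode <- seq_len(nrow(sub))
    names(rowByNode) <- as.character(sub$Node)
    walk <- function(node, lo, hi) {
      i <- rowByNode[[as.character(node)]]
      if (sub$Feature[i] == "Leaf") {
        cons <- which(is.finite(lo) | is.finite(hi))
        leafValue[length(leafValue) + 1L] <<- sub$Gain[i]
        consFeat <<- c(consFeat, cons - 1L)
        consLo <<- c(consLo, lo[cons])
        consHi <<- c(consHi, hi[cons])
        consStart[length(consStart) + 1L] <<- length(consFeat)
        return(invisible())
      }
      f <- match(sub$Feature[i], model@featureNames)
      s <- sub$Split[i]
      yesNode <- sub$Node[match(sub$Yes[i], sub$ID)]
      noNode <- sub$Node[match(sub$No[i], sub$ID)]
      hi2 <- hi; hi2[f] <- min(hi2[f], s)
      walk(yesNode, lo, hi2)
      lo2 <- lo; lo2[f] <- max(lo2[f], s)
      walk(noNode, lo2, hi)
    }
    walk(0L, rep(-Inf, nF), rep(Inf, nF))
  }
  out <- list(leafValue = leafValue,
              consStart = as.integer(consStart),
              consFeat = consFeat, consLo = consLo, consHi = consHi)
  ## double-precision anchor for the booster's constant bias
  m <- predict(model@booster,
               xgboost::xgb.DMatrix(calibrationRow), outputmargin = TRUE)
  s <- treeSumCpp(out$consStart, out$leafValue, out$consFeat,
                  out$consLo, out$consHi, calibrationRow)
  out$offset <- as.numeric(m - s)
  out
}

prepareReference <- function(model, referenceSet, maxReference, seed) {
  refs <- classifierMatrix(model, referenceSet)
  if (!nrow(refs)) stop("reference set must be non-empty")
  if (nrow(refs) > maxReference)
    refs <- withSeed(seed, refs[sample(nrow(refs), maxReference), , drop = FALSE])
  refs
}

#' Explain one prediction with exact interventional Shapley values
#'
#' @param model a [ClassifierModel-class].
#' @param row a single sample: named numeric vector, one-row matrix /
#'   data.frame or one-row [OocyteFeatureSet-class].
#' @param referenceSet background samples defining the prior expectation
#'   (typically the training split).
#' @param maxReference cap on reference rows (seeded subsample above it).
#' @param seed integer seed for the reference subsample.
#' @param rowId identifier stored in the explanation.
#' @return an [Explanation-class]; \code{baseValue + sum(attributions)}
#'   equals the sample logit \code{fx} exactly.
#' @export
explainSample <- function(model, row, referenceSet, maxReference = 1000L,
                          seed = 1L, rowId = "sample") {
  stopifnot(is(model, "ClassifierModel"))
  X <- classifierMatrix(model, row)
  if (nrow(X) != 1) stop("row must be a single sample")
  refs <- prepareReference(model, referenceSet, maxReference, seed)
  lt <- parseBoosterLeaves(model, refs[1, , drop = FALSE])
  phi <- treeShapInterventionalCpp(lt$consStart, lt$leafValue, lt$consFeat,
                                   lt$consLo, lt$consHi, as.numeric(X[1, ]),
                                   refs)
  names(phi) <- model@featureNames
  base <- mean(treeSumCpp(lt$consStart, lt$leafValue, lt$consFeat,
                          lt$consLo, lt$consHi, refs)) + lt$offset
  fx <- as.numeric(treeSumCpp(lt$consStart, lt$leafValue, lt$consFeat,
                              lt$consLo, lt$consHi, X)) + lt$offset
  new("Explanation", baseValue = base, attributions = phi, fx = fx,
      probability = plogis(fx), rowId = as.character(rowId))
}

#' @describeIn Explanation-class compact display
#' @param object an Explanation
#' @export
setMethod("show", "Explanation", function(object) {
  cat(sprintf("Explanation [%s]: base %.4f -> f(x) %.4f (p = %.4f)\n",
              object@rowId, object@baseValue, object@fx, object@probability))
  top <- head(object@attributions[order(-abs(object@attributions))], 5)
  for (nm in names(top))
    cat(sprintf("  %+0.4f  %s\n", top[[nm]], nm))
})

#' Global feature importance: mean absolute Shapley value (MASV)
#'
#' Averages the absolute interventional Shapley attribution of every
#' feature over a dataset; higher values indicate greater importance to
#' the model's predictions.  Ordering is descending with ties broken by
#' feature name.
#'
#' @param model a [ClassifierModel-class].
#' @param data samples to explain (matrix, data.frame or
#'   [OocyteFeatureSet-class]).
#' @param referenceSet background samples; defaults to \code{data}.
#' @param maxReference cap on reference rows (seeded subsample).
#' @param seed integer seed.
#' @return data.frame with columns \code{feature}, \code{masv}, ordered
#'   by decreasing importance.
#' @export
masvRanking <- function(model, data, referenceSet = NULL,
                        maxReference = 200L, seed = 1L) {
  X <- classifierMatrix(model, data)
  if (is.null(referenceSet)) referenceSet <- X
  refs <- prepareReference(model, referenceSet, maxReference, seed)
  lt <- parseBoosterLeaves(model, refs[1, , drop = FALSE])
  absSum <- numeric(ncol(X))
  for (i in seq_len(nrow(X))) {
    phi <- treeShapInterventionalCpp(lt$consStart, lt$leafValue, lt$consFeat,
                                     lt$consLo, lt$consHi,
                                     as.numeric(X[i, ]), refs)
    absSum <- absSum + abs(phi)
  }
  masv <- absSum / nrow(X)
  out <- data.frame(feature = model@featureNames, masv = masv)
  out <- out[order(-out$masv, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Export a waterfall record of an explanation
#'
#' Orders features by absolute attribution; contributions beyond
#' \code{topK} are aggregated into a single \code{"other"} term so the
#' additivity identity (base value plus all listed contributions equals
#' f(x)) is preserved exactly.
#'
#' @param explanation an [Explanation-class].
#' @param topK number of named features to retain (>= 1).
#' @return list ready for JSON serialisation: \code{row_id},
#'   \code{base_value}, \code{fx}, \code{probability} and a
#'   \code{contributions} data.frame (feature, attribution).
#' @export
exportWaterfall <- function(explanation, topK = 10L) {
  stopifnot(is(explanation, "Explanation"))
  if (topK < 1) stop("topK must be at least 1")
  phi <- explanation@attributions
  ord <- order(-abs(phi), names(phi))
  phi <- phi[ord]
  if (topK < length(phi)) {
    other <- sum(phi[(topK + 1):length(phi)])
    contrib <- data.frame(feature = c(names(phi)[seq_len(topK)], "other"),
                          attribution = c(unname(phi[seq_len(topK)]), other))
  } else {
    contrib <- data.frame(feature = names(phi), attribution = unname(phi))
  }
  list(row_id = explanation@rowId,
       base_value = explanation@baseValue,
       fx = explanation@fx,
       probability = explanation@probability,
       contributions = contrib)
}

#' Write / read waterfall JSON
#' @param waterfall a record from [exportWaterfall()].
#' @param path file path.
#' @return \code{readWaterfall} returns the parsed record.
#' @export
writeWaterfall <- function(waterfall, path) {
  jsonlite::write_json(waterfall, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeWaterfall
#' @export
readWaterfall <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
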