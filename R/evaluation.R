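## Evaluation statistics: ROC AUC (Mann-Whitney form), sensitivity /
## specificity, the paired DeLong test for correlated ROC curves, Welch's
## t feature screening, PCA reduction, feature-group ablations and
## subgroup analysis.

#' ROC area under the curve
#'
#' Rank-based computation of the Mann-Whitney statistic
#' \eqn{P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)}; ties contribute one half.
#' Invariant under strictly monotone transformations of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1 outcome labels.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  stopIfNot01Labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Sensitivity and specificity of predicted labels
#'
#' Sensitivity = TP/(TP+FN); specificity = TN/(TN+FP).  When a rate is
#' undefined (no positives, resp. no negatives, in the truth) it is
#' reported as \code{NA}, never silently as 0.
#'
#' @param labelsPred,labelsTrue binary 0/1 vectors.
#' @return named numeric: \code{sensitivity}, \code{specificity}.
#' @export
sensSpec <- function(labelsPred, labelsTrue) {
  stopIfNot01Labels(labelsPred); stopIfNot01Labels(labelsTrue)
  if (length(labelsPred) != length(labelsTrue)) stop("length mismatch")
  tp <- sum(labelsPred == 1 & labelsTrue == 1)
  fn <- sum(labelsPred == 0 & labelsTrue == 1)
  tn <- sum(labelsPred == 0 & labelsTrue == 0)
  fp <- sum(labelsPred == 1 & labelsTrue == 0)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Performance report for one score vector
#'
#' @param scores numeric probabilities/scores.
#' @param labels binary 0/1 truth.
#' @param threshold decision threshold; a prediction is positive strictly
#'   above it (a score exactly at the threshold is negative, consistent
#'   with "positive iff the logit is positive").
#' @param subgroup label for the report.
#' @return an [EvalReport-class].
#' @export
evalReport <- function(scores, labels, threshold = 0.5, subgroup = "overall") {
  stopIfNot01Labels(labels)
  pred <- as.integer(scores > threshold)
  ss <- sensSpec(pred, labels)
  auc <- if (length(unique(labels)) == 2) rocAuc(scores, labels) else NA_real_
  new("EvalReport", auc = auc,
      sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
      n = length(labels),
      counts = c(tp = sum(pred == 1 & labels == 1),
                 fp = sum(pred == 1 & labels == 0),
                 tn = sum(pred == 0 & labels == 0),
                 fn = sum(pred == 0 & labels == 1)),
      subgroup = subgroup)
}

#' @describeIn EvalReport-class compact display
#' @param object an EvalReport
#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s]: n=%d AUC=%.3f sens=%.3f spec=%.3f\n",
              object@subgroup, object@n, object@auc,
              object@sensitivity, object@specificity))
})

## DeLong placement values: for each positive, the fraction of negatives
## it beats (ties half); and symmetrically for negatives
delongPlacements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  rAll <- rank(c(pos, neg), ties.method = "average")
  rPos <- rank(pos, ties.method = "average")
  rNeg <- rank(neg, ties.method = "average")
  v10 <- (rAll[seq_len(m)] - rPos) / n
  v01 <- 1 - (rAll[m + seq_len(n)] - rNeg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single AUC
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @return estimated variance of the empirical AUC.
#' @export
delongVariance <- function(scores, labels) {
  stopIfNot01Labels(labels)
  pl <- delongPlacements(scores, labels)
  var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
}

#' Paired DeLong test for two correlated ROC AUCs
#'
#' Both models score the same samples; the placement-value covariance
#' estimator of DeLong, DeLong and Clarke-Pearson yields the variance of
#' the AUC difference, and a two-sided normal p-value is reported.
#'
#' @param scoresA,scoresB numeric score vectors over the same samples.
#' @param labels binary 0/1 truth.
#' @return a [DeLongResult-class].
#' @export
delongPaired <- function(scoresA, scoresB, labels) {
  stopIfNot01Labels(labels)
  if (length(scoresA) != length(scoresB) || length(scoresA) != length(labels))
    stop("scoresA, scoresB and labels must be aligned")
  if (sum(labels == 1) < 2 || sum(labels == 0) < 2)
    stop("need at least two samples of each class")
  pa <- delongPlacements(scoresA, labels)
  pb <- delongPlacements(scoresB, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- var(pa$v10) + var(pb$v10) - 2 * stats::cov(pa$v10, pb$v10)
  s01 <- var(pa$v01) + var(pb$v01) - 2 * stats::cov(pa$v01, pb$v01)
  vd <- s10 / m + s01 / n
  d <- pa$auc - pb$auc
  if (vd <= 0) {
    if (abs(d) < 1e-12)
      return(new("DeLongResult", auc1 = pa$auc, auc2 = pb$auc,
                 varDiff = 0, z = 0, p = 1))
    stop("zero estimated variance with unequal AUCs: numerical degeneracy")
  }
  z <- d / sqrt(vd)
  new("DeLongResult", auc1 = pa$auc, auc2 = pb$auc, varDiff = vd,
      z = z, p = 2 * pnorm(-abs(z)))
}

#' @describeIn DeLongResult-class compact display
#' @param object a DeLongResult
#' @export
setMethod("show", "DeLongResult", function(object) {
  cat(sprintf("DeLong paired test: AUC %.4f vs %.4f, z=%.3f, p=%.4g\n",
              object@auc1, object@auc2, object@z, object@p))
})

#' Welch's unequal-variance t-test
#'
#' Thin wrapper around the Welch two-sample t-test with
#' Welch-Satterthwaite degrees of freedom, used to screen features
#' between outcome-positive and outcome-negative oocytes.
#'
#' @param valuesPos,valuesNeg numeric vectors, each of length >= 2.
#' @return named list with \code{t}, \code{df}, \code{p}.
#' @export
welchT <- function(valuesPos, valuesNeg) {
  if (length(valuesPos) < 2 || length(valuesNeg) < 2)
    stop("each group needs at least two values")
  if (var(valuesPos) == 0 && var(valuesNeg) == 0) {
    if (mean(valuesPos) == mean(valuesNeg))
      return(list(t = 0, df = NA_real_, p = 1))
    stop("zero variance in both groups: t undefined")
  }
  ht <- t.test(valuesPos, valuesNeg, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Welch screening of every feature column by outcome
#'
#' @param fs an [OocyteFeatureSet-class].
#' @return data.frame with one row per feature: t, df, p (NA for
#'   zero-variance columns), ordered by p.
#' @export
welchScreen <- function(fs) {
  stopifnot(is(fs, "OocyteFeatureSet"))
  y <- outcomeLabels(fs)
  out <- lapply(colnames(fs@features), function(cc) {
    x <- fs@features[[cc]]
    res <- tryCatch(welchT(x[y == 1], x[y == 0]),
                    error = function(e) list(t = NA_real_, df = NA_real_,
                                             p = NA_real_))
    data.frame(feature = cc, t = res$t, df = res$df, p = res$p)
  })
  out <- do.call(rbind, out)
  out[order(out$p), ]
}

#' PCA reduction to a target explained variance
#'
#' Features are standardised (constant columns dropped with a warning),
#' then the smallest number of principal components whose cumulative
#' explained variance reaches the threshold is retained.
#'
#' @param x numeric matrix or [OocyteFeatureSet-class].
#' @param explainedVariance threshold in (0, 1].
#' @return list with \code{scores} (reduced matrix), \code{nComponents},
#'   \code{explained} (cumulative fractions) and the \code{prcomp} fit.
#' @export
pcaReduce <- function(x, explainedVariance = 0.95) {
  if (is(x, "OocyteFeatureSet")) x <- featureMatrix(x)
  if (ncol(x) < 2) stop("need at least two features")
  if (explainedVariance <= 0 || explainedVariance > 1)
    stop("explainedVariance must lie in (0, 1]")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant columns before PCA: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  fit <- prcomp(x, center = TRUE, scale. = TRUE)
  cum <- cumsum(fit$sdev^2) / sum(fit$sdev^2)
  k <- which(cum >= explainedVariance - 1e-9)[1]
  list(scores = fit$x[, seq_len(k), drop = FALSE], nComponents = k,
       explained = cum, fit = fit)
}

#' Feature-group ablation analysis
#'
#' Retrains the classifier without each named feature group, evaluates
#' every retrained model on the identical test rows, and compares each to
#' the full model with the paired DeLong test.
#'
#' @param fs an [OocyteFeatureSet-class].
#' @param split a [SplitAssignment-class].
#' @param groups character vector of groups understood by
#'   [dropFeatureGroups()].
#' @param fullModel optionally a pre-trained full [ClassifierModel-class]
#'   (retrained when omitted).
#' @param ... forwarded to [trainClassifier()].
#' @return data.frame with one row per group: test AUC of the ablated
#'   model, full-model AUC, DeLong z and p.
#' @export
ablationEval <- function(fs, split, groups, fullModel = NULL, ...) {
  if (!length(groups)) stop("no groups to ablate")
  te <- splitIdx(split, "test")
  if (!length(te)) stop("split contains no test rows")
  y <- outcomeLabels(fs)[te]
  if (is.null(fullModel)) fullModel <- trainClassifier(fs, split, ...)
  pFull <- predict(fullModel, fs[te])$probability
  aucFull <- rocAuc(pFull, y)
  rows <- lapply(groups, function(g) {
    red <- dropFeatureGroups(fs, g)
    mod <- trainClassifier(red, split, ...)
    p <- predict(mod, red[te])$probability
    dl <- delongPaired(p, pFull, y)
    data.frame(group = g, auc = dl@auc1, aucFull = aucFull,
               deltaAuc = dl@auc1 - aucFull, z = dl@z, p = dl@p)
  })
  do.call(rbind, rows)
}

#' Clinical age bins
#'
#' The standard ICSI age strata: <30, 30--34, 35--37, 38--39, >=40
#' (closed integer bins).
#'
#' @param age numeric/integer ages.
#' @return factor of bin labels.
#' @export
ageBin <- function(age) {
  cut(age, breaks = c(-Inf, 29, 34, 37, 39, Inf),
      labels = c("<30", "30-34", "35-37", "38-39", ">=40"))
}

#' Subgroup performance analysis
#'
#' Evaluates the score vector within subgroups (clinical age bins or
#' clinic site) and compares each subgroup AUC with the AUC on the whole
#' set.  Because every subgroup is nested in the overall set the two AUCs
#' are not independent; the default comparison therefore uses a seeded
#' patient-level (cluster) bootstrap of the AUC difference, with a
#' DeLong-variance unpaired z-test available as an alternative (reported
#' with the caveat that it ignores the nesting).  An optional age filter
#' excludes oocytes above a cut-off (used for external-validation style
#' analyses where oocytes > 43 years are removed).
#'
#' @param scores numeric scores.
#' @param labels binary 0/1 truth.
#' @param meta data.frame with \code{oocyte_age}, \code{clinic},
#'   \code{patient_id} aligned with scores.
#' @param by \code{"age"} or \code{"clinic"}.
#' @param excludeAgeOver optional numeric; oocytes with age strictly above
#'   it are dropped before any analysis.
#' @param method \code{"bootstrap"} (nesting-aware, default) or
#'   \code{"unpaired"}.
#' @param B bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @param threshold decision threshold for sensitivity/specificity.
#' @return data.frame, one row per subgroup plus an "overall" row:
#'   n, nPos, auc, sensitivity, specificity, z, p (NA where an AUC is
#'   undefined).
#' @export
subgroupEval <- function(scores, labels, meta, by = c("age", "clinic"),
                         excludeAgeOver = NULL,
                         method = c("bootstrap", "unpaired"),
                         B = 500L, seed = 1L, threshold = 0.5) {
  by <- match.arg(by); method <- match.arg(method)
  stopIfNot01Labels(labels)
  if (nrow(meta) != length(scores)) stop("meta and scores are not aligned")
  keep <- rep(TRUE, length(scores))
  if (!is.null(excludeAgeOver)) keep <- meta$oocyte_age <= excludeAgeOver
  scores <- scores[keep]; labels <- labels[keep]
  meta <- meta[keep, , drop = FALSE]
  grp <- if (by == "age") ageBin(meta$oocyte_age) else factor(meta$clinic)
  overall <- evalReport(scores, labels, threshold)
  aucAll <- overall@auc
  rows <- list(data.frame(subgroup = "overall", n = overall@n,
                          nPos = sum(labels == 1), auc = aucAll,
                          sensitivity = overall@sensitivity,
                          specificity = overall@specificity,
                          z = NA_real_, p = NA_real_))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (!length(idx)) next
    rep <- evalReport(scores[idx], labels[idx], threshold, subgroup = g)
    z <- p <- NA_real_
    if (!is.na(rep@auc)) {
      if (method == "unpaired") {
        v <- delongVariance(scores[idx], labels[idx]) +
          delongVariance(scores, labels)
        z <- (rep@auc - aucAll) / sqrt(v)
        p <- 2 * pnorm(-abs(z))
      } else {
        idxByPat <- split(seq_along(scores), meta$patient_id)
        diffs <- withSeed(seed, {
          vapply(seq_len(B), function(b) {
            bp <- sample(names(idxByPat), length(idxByPat), replace = TRUE)
            take <- unlist(idxByPat[bp], use.names = FALSE)
            lb <- labels[take]; sc <- scores[take]
            sub <- grp[take] == g
            if (length(unique(lb)) < 2 || length(unique(lb[sub])) < 2)
              return(NA_real_)
            rocAuc(sc[sub], lb[sub]) - rocAuc(sc, lb)
          }, numeric(1))
        })
        diffs <- diffs[is.finite(diffs)]
        if (length(diffs) >= B / 2 && sd(diffs) > 0) {
          z <- (rep@auc - aucAll) / sd(diffs)
          p <- 2 * pnorm(-abs(z))
        }
      }
    }
    rows[[length(rows) + 1L]] <-
      data.frame(subgroup = g, n = rep@n, nPos = sum(labels[idx] == 1),
                 auc = rep@auc, sensitivity = rep@sensitivity,
                 specificity = rep@specificity, z = z, p = p)
  }
  do.call(rbind, rows)
}
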