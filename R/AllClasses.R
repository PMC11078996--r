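## S4 class definitions for the central data objects.

#' PhantomSpec: geometry and rendering parameters of a synthetic oocyte
#'
#' Describes one family of nested-ellipse oocyte phantoms.  All lengths are
#' in pixels; the phantom carries no micron calibration because every
#' downstream feature is a dimensionless ratio.  Regions are nested
#' strictly: ooplasm inside the perivitelline space (PVS) outer boundary
#' inside the zona pellucida (ZP) outer boundary.
#'
#' @slot imageSize integer, side length of the square image.
#' @slot zpOuterAxes numeric(2), semi-major/semi-minor axes of the ZP outer
#'   ellipse (px).
#' @slot zpThickness numeric, radial thickness of the ZP shell (px).
#' @slot pvsOuterScale numeric in (0,1), PVS outer ellipse axes as a
#'   fraction of the ZP inner ellipse.
#' @slot ooplasmScale numeric in (0,1), ooplasm axes as a fraction of the
#'   PVS outer ellipse.
#' @slot centerOffsetSd numeric, s.d. (px) of the random offset of each
#'   inner region's centre relative to its enclosing region.
#' @slot rotation numeric, in-plane rotation in radians; \code{NA} draws a
#'   uniform rotation per oocyte.
#' @slot elongationJitter numeric, s.d. of the per-region, area-preserving
#'   aspect-ratio jitter (semi-major multiplied by \code{1+e}, semi-minor
#'   divided by it).
#' @slot scaleJitter numeric, s.d. of the multiplicative jitter applied to
#'   \code{pvsOuterScale} and \code{ooplasmScale} per oocyte; this is what
#'   makes between-region area ratios vary across oocytes.
#' @slot boundaryNoiseAmplitude numeric, amplitude (px) of the low-order
#'   Fourier perturbation of each boundary radius; 0 gives exact ellipses.
#' @slot boundaryNoiseModes integer vector of angular modes perturbed.
#' @slot intensityLevels named numeric(4), mean 8-bit grey level per class
#'   (\code{background}, \code{ooplasm}, \code{pvs}, \code{zp}).
#' @slot noiseSd numeric, s.d. of additive Gaussian pixel noise (grey
#'   levels).
#' @seealso [phantomSpec()], [generatePhantom()]
#' @export
setClass("PhantomSpec", slots = c(
  imageSize = "integer",
  zpOuterAxes = "numeric",
  zpThickness = "numeric",
  pvsOuterScale = "numeric",
  ooplasmScale = "numeric",
  centerOffsetSd = "numeric",
  rotation = "numeric",
  elongationJitter = "numeric",
  scaleJitter = "numeric",
  boundaryNoiseAmplitude = "numeric",
  boundaryNoiseModes = "integer",
  intensityLevels = "numeric",
  noiseSd = "numeric"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@imageSize < 32L)
    msg <- c(msg, "imageSize must be at least 32 px")
  ax <- object@zpOuterAxes
  if (length(ax) != 2L || any(ax <= 0))
    msg <- c(msg, "zpOuterAxes must be two positive semi-axes")
  if (object@zpThickness <= 0 || object@zpThickness >= min(ax))
    msg <- c(msg, "zpThickness must be positive and smaller than the ZP semi-minor axis")
  for (s in c("pvsOuterScale", "ooplasmScale")) {
    v <- slot(object, s)
    if (v <= 0 || v >= 1)
      msg <- c(msg, sprintf("%s must lie strictly in (0, 1) for nested regions", s))
  }
  if (any(object@zpOuterAxes + object@zpThickness >
          (object@imageSize - 1) / 2 - 2))
    msg <- c(msg, "ZP ellipse does not fit inside the image with a 2 px margin")
  if (object@elongationJitter < 0 || object@scaleJitter < 0 ||
      object@boundaryNoiseAmplitude < 0 || object@noiseSd < 0 ||
      object@centerOffsetSd < 0)
    msg <- c(msg, "jitter, noise and offset parameters must be non-negative")
  ## the sampler clamps jitters per oocyte to preserve nesting, so the
  ## spec only needs the *base* geometry to nest with room for the
  ## boundary-noise budget
  zpInner <- ax - object@zpThickness
  pvsBase <- object@pvsOuterScale * zpInner
  ooBase <- object@ooplasmScale * pvsBase
  slack <- 3 * object@boundaryNoiseAmplitude + 0.5
  if (length(ax) == 2L && all(ax > 0) && object@zpThickness < min(ax)) {
    if (ooBase[1] + slack >= pvsBase[1] || ooBase[2] + slack >= pvsBase[2])
      msg <- c(msg, "base geometry leaves no room between ooplasm and PVS boundary (ooplasmScale too close to 1 for the boundary noise)")
    if (pvsBase[1] + slack + 1.5 >= ax[1] || pvsBase[2] + slack + 1.5 >= ax[2])
      msg <- c(msg, "base geometry leaves no visible ZP ring (pvsOuterScale/zpThickness too large for the boundary noise)")
  }
  lv <- object@intensityLevels
  if (length(lv) != 4L || is.null(names(lv)) ||
      !setequal(names(lv), c("background", "ooplasm", "pvs", "zp")))
    msg <- c(msg, "intensityLevels must be named background/ooplasm/pvs/zp")
  if (length(msg)) msg else TRUE
})

#' OutcomeModel: logistic model linking oocyte features to blastocyst outcome
#'
#' A synthetic stand-in for the unobservable clinical outcome process: the
#' probability that an oocyte develops into a blastocyst is
#' \code{plogis(intercept + sum(coefficients * features))}, and outcomes are
#' drawn Bernoulli from it.  Coefficient names refer to columns of the
#' assembled feature table, so the generator's drivers are by construction
#' recoverable by the downstream classifier and attribution machinery.
#'
#' @slot intercept numeric scalar on the logit scale.
#' @slot coefficients named numeric vector of per-feature logit slopes.
#' @seealso [outcomeModel()], [generateCohortDataset()]
#' @export
setClass("OutcomeModel", slots = c(
  intercept = "numeric",
  coefficients = "numeric"
))

setValidity("OutcomeModel", function(object) {
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a finite scalar")
  if (length(object@coefficients) &&
      (is.null(names(object@coefficients)) ||
       any(!nzchar(names(object@coefficients)))))
    return("coefficients must be a named numeric vector")
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  TRUE
})

#' RegionGeometry: filled-contour measurements of one oocyte region
#'
#' Measurements follow the filled-outer-contour convention: each region's
#' area, perimeter, fitted-ellipse axes and convex-hull area refer to the
#' area enclosed by the region's \emph{outer} boundary, so the PVS geometry
#' covers ooplasm plus PVS annulus and the ZP geometry covers the whole
#' oocyte.  Between-region ratios of such measurements lie in (0, 1].
#'
#' @slot region character, one of \code{"ooplasm"}, \code{"pvs"},
#'   \code{"zp"} (or \code{"custom"} for analytic constructions).
#' @slot area numeric, enclosed area A (px^2).
#' @slot perimeter numeric, outer contour length Lp (px).
#' @slot majorAxis numeric, major axis Lmaj of the best-fit ellipse (px).
#' @slot minorAxis numeric, minor axis Lmin (px).
#' @slot hullArea numeric, area of the convex hull Ahull (px^2).
#' @seealso [RegionGeometry()], [regionGeometry()], [shapeDescriptors()]
#' @export
setClass("RegionGeometry", slots = c(
  region = "character",
  area = "numeric",
  perimeter = "numeric",
  majorAxis = "numeric",
  minorAxis = "numeric",
  hullArea = "numeric"
))

setValidity("RegionGeometry", function(object) {
  v <- c(object@area, object@perimeter, object@majorAxis,
         object@minorAxis, object@hullArea)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all measurements must be finite and strictly positive")
  if (object@minorAxis > object@majorAxis * (1 + 1e-9))
    return("minorAxis must not exceed majorAxis")
  ## sub-pixel contours may overshoot the hull by a sliver of raster noise
  if (object@area > object@hullArea * (1 + 1e-6))
    return("area must not exceed hull area")
  TRUE
})

#' OocyteStudy: a generated cohort-structured phantom dataset
#'
#' One synthetic study: per-oocyte identifiers and clinical covariates,
#' measured region geometry, the latent true outcome probability from the
#' generating [OutcomeModel], and the drawn binary outcome.  Images are only
#' retained on request.
#'
#' @slot oocytes data.frame with one row per oocyte (ids, clinic, age,
#'   cohort size, outcome, true probability, measured and analytic
#'   geometry).
#' @slot spec the [PhantomSpec-class] used.
#' @slot outcomeModel the generating [OutcomeModel-class].
#' @slot seed integer seed of the draw.
#' @slot images list of rendered images (possibly empty).
#' @slot labels list of label images (possibly empty).
#' @export
setClass("OocyteStudy", slots = c(
  oocytes = "data.frame",
  spec = "PhantomSpec",
  outcomeModel = "OutcomeModel",
  seed = "integer",
  images = "list",
  labels = "list"
))

#' OocyteFeatureSet: the assembled model input table
#'
#' Rows are oocytes; feature columns carry group tags in
#' \code{ooplasm/pvs/zp/relative/cohort_avg/cohort_rel/clinical}.  The
#' default enumeration has 50 columns: 12 mask-specific descriptors
#' (3 regions x aspect ratio, circularity, roundness, solidity), 12
#' between-region ratios (3 pairs x major axis, minor axis, perimeter,
#' area), their 12 cohort averages and 12 cohort-relative deviations, plus
#' the two clinical features oocyte age and number of MII oocytes in the
#' retrieval-cycle cohort.
#'
#' @slot features data.frame of numeric feature columns.
#' @slot schema data.frame with columns \code{column}, \code{group},
#'   \code{regions} (slash-separated regions a column involves).
#' @slot meta data.frame of per-oocyte identifiers (oocyte_id, patient_id,
#'   cycle_id, clinic) and the binary \code{outcome}.
#' @seealso [assembleFeatureTable()], [dropFeatureGroups()]
#' @export
setClass("OocyteFeatureSet", slots = c(
  features = "data.frame",
  schema = "data.frame",
  meta = "data.frame"
))

setValidity("OocyteFeatureSet", function(object) {
  msg <- character()
  if (nrow(object@features) != nrow(object@meta))
    msg <- c(msg, "features and meta must have the same number of rows")
  if (!identical(sort(colnames(object@features)),
                 sort(object@schema$column)))
    msg <- c(msg, "schema must describe exactly the feature columns")
  if (anyNA(object@features))
    msg <- c(msg, "feature columns must not contain missing values")
  need <- c("oocyte_id", "patient_id", "cycle_id", "clinic", "outcome")
  if (!all(need %in% colnames(object@meta)))
    msg <- c(msg, paste("meta must contain", paste(need, collapse = ", ")))
  clin <- object@schema$column[object@schema$group == "clinical"]
  if (length(clin) && !setequal(clin, c("oocyte_age", "n_mii_oocytes")))
    msg <- c(msg, "clinical columns must be exactly oocyte_age and n_mii_oocytes")
  if (length(msg)) msg else TRUE
})

#' SplitAssignment: patient-level train/validation/test assignment
#'
#' @slot split character vector, one of \code{train}, \code{validation},
#'   \code{test} per oocyte row.
#' @slot patientId character vector aligned with \code{split}.
#' @slot fractions named numeric(3), requested oocyte-level fractions.
#' @slot seed integer.
#' @seealso [patientSplit()]
#' @export
setClass("SplitAssignment", slots = c(
  split = "character",
  patientId = "character",
  fractions = "numeric",
  seed = "integer"
))

setValidity("SplitAssignment", function(object) {
  if (length(object@split) != length(object@patientId))
    return("split and patientId must be aligned")
  if (!all(object@split %in% c("train", "validation", "test")))
    return("split labels must be train/validation/test")
  tab <- table(object@patientId, object@split)
  if (any(rowSums(tab > 0) > 1L))
    return("a patient appears in more than one split")
  TRUE
})

#' ClassifierModel: trained gradient-boosted outcome classifier
#'
#' Wraps an xgboost booster together with its feature schema and training
#' configuration.  Predictions expose both the logit f(x) and the
#' probability \code{plogis(f(x))}; the predicted label is positive exactly
#' when the logit is positive (probability above 0.5).
#'
#' @slot booster the fitted \code{xgb.Booster}.
#' @slot featureNames character, training column order.
#' @slot params list of training parameters.
#' @slot bestIteration integer, early-stopped best round (NA if unused).
#' @slot nTrainPos,nTrainNeg integer class counts seen in training.
#' @seealso [trainClassifier()], [predict,ClassifierModel-method]
#' @export
setClass("ClassifierModel", slots = c(
  booster = "ANY",
  featureNames = "character",
  params = "list",
  bestIteration = "integer",
  nTrainPos = "integer",
  nTrainNeg = "integer"
))

#' Explanation: additive Shapley attribution of one prediction
#'
#' Attributions live in logit space: \code{baseValue} is the mean model
#' logit over the reference set (the prior expectation) and
#' \code{baseValue + sum(attributions)} equals the sample's logit
#' \code{fx}; the probability is \code{plogis(fx)}.
#'
#' @slot baseValue numeric, prior expectation (logit).
#' @slot attributions named numeric, per-feature signed contributions.
#' @slot fx numeric, resulting logit.
#' @slot probability numeric, \code{plogis(fx)}.
#' @slot rowId character identifier of the explained row.
#' @seealso [explainSample()], [exportWaterfall()]
#' @export
setClass("Explanation", slots = c(
  baseValue = "numeric",
  attributions = "numeric",
  fx = "numeric",
  probability = "numeric",
  rowId = "character"
))

setValidity("Explanation", function(object) {
  if (abs(object@baseValue + sum(object@attributions) - object@fx) > 1e-6)
    return("local accuracy violated: baseValue + sum(attributions) != fx")
  if (abs(object@probability - plogis(object@fx)) > 1e-12)
    return("probability must equal plogis(fx)")
  TRUE
})

#' DeLongResult: paired comparison of two correlated ROC AUCs
#'
#' @slot auc1,auc2 numeric AUCs of the two score vectors.
#' @slot varDiff numeric, estimated variance of \code{auc1 - auc2}.
#' @slot z numeric, normal test statistic.
#' @slot p numeric, two-sided p-value.
#' @seealso [delongPaired()]
#' @export
setClass("DeLongResult", slots = c(
  auc1 = "numeric",
  auc2 = "numeric",
  varDiff = "numeric",
  z = "numeric",
  p = "numeric"
))

setValidity("DeLongResult", function(object) {
  if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
  d <- object@auc1 - object@auc2
  if (abs(d) > 1e-12 && abs(object@z) > 1e-12 && sign(object@z) != sign(d))
    return("sign of z must match sign of auc1 - auc2")
  TRUE
})

#' EvalReport: classification performance on one (sub)group
#'
#' @slot auc numeric AUC (NA when the group has a single class).
#' @slot sensitivity,specificity numeric (NA when undefined).
#' @slot n integer number of samples.
#' @slot counts named integer(4): tp, fp, tn, fn.
#' @slot subgroup character label ("overall" when unstratified).
#' @seealso [evalReport()], [subgroupEval()]
#' @export
setClass("EvalReport", slots = c(
  auc = "numeric",
  sensitivity = "numeric",
  specificity = "numeric",
  n = "integer",
  counts = "integer",
  subgroup = "character"
))

setValidity("EvalReport", function(object) {
  if (sum(object@counts) != object@n)
    return("counts must sum to n")
  ok <- function(x) is.na(x) || (x >= 0 && x <= 1)
  if (!ok(object@auc) || !ok(object@sensitivity) || !ok(object@specificity))
    return("auc, sensitivity, specificity must lie in [0, 1] or be NA")
  TRUE
})

#' SegmentationReport: per-class IoU over a set of image pairs
#'
#' @slot perImage data.frame with columns \code{image}, \code{class},
#'   \code{iou}.
#' @slot summary data.frame with columns \code{class}, \code{mean},
#'   \code{sd}, \code{n}.
#' @seealso [evaluateSegmentation()]
#' @export
setClass("SegmentationReport", slots = c(
  perImage = "data.frame",
  summary = "data.frame"
))

setValidity("SegmentationReport", function(object) {
  if (nrow(object@perImage) &&
      (min(object@perImage$iou) < 0 || max(object@perImage$iou) > 1))
    return("per-image IoU values must lie in [0, 1]")
  for (i in seq_len(nrow(object@summary))) {
    cls <- object@summary$class[i]
    v <- object@perImage$iou[object@perImage$class == cls]
    if (length(v) && (object@summary$mean[i] < min(v) - 1e-12 ||
                      object@summary$mean[i] > max(v) + 1e-12))
      return("class mean must lie within the per-image range")
  }
  TRUE
})
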