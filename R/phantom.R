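## Synthetic oocyte phantom generation.
##
## A phantom is three nested regions -- ooplasm inside the perivitelline
## space (PVS) inside the zona pellucida (ZP) -- each bounded by an ellipse
## whose radius may carry a low-order Fourier perturbation.  Regions are
## painted outer-to-inner (ZP, then PVS, then ooplasm) so the label image
## is single-valued per pixel and nesting is guaranteed by construction.
## Pixel convention: 0-based coordinates, pixel centres, x along columns
## and y along rows; all geometry is in pixel units.

#' Construct a phantom specification
#'
#' Defaults are calibrated so that the phantom population reproduces the
#' feature scales observed in clinical MII oocyte morphometry: a mean
#' ooplasm-vs-ZP major-axis ratio of about 0.70 and a mean ooplasm-vs-PVS
#' area ratio of about 0.81, with realistic spread injected through
#' per-region aspect jitter (roundness variation of s.d. about 0.04) and
#' nested-scale jitter (area-ratio variation of s.d. about 0.05).
#'
#' @param imageSize side of the square image in pixels.
#' @param zpOuterAxes semi-major/semi-minor axes of the ZP outer ellipse.
#' @param zpThickness ZP shell thickness in px.
#' @param pvsOuterScale PVS outer axes as a fraction of the ZP inner
#'   ellipse, in (0,1).
#' @param ooplasmScale ooplasm axes as a fraction of the PVS outer ellipse,
#'   in (0,1).
#' @param centerOffsetSd s.d. (px) of inner-region centre offsets.
#' @param rotation fixed rotation in radians, or \code{NA} to draw
#'   uniformly per oocyte.
#' @param elongationJitter s.d. of per-region area-preserving aspect jitter.
#' @param scaleJitter s.d. of multiplicative jitter on the nested scales.
#' @param boundaryNoiseAmplitude amplitude (px) of boundary irregularity;
#'   0 gives exact ellipses.
#' @param boundaryNoiseModes integer angular modes of the perturbation.
#' @param intensityLevels named mean grey levels per class.
#' @param noiseSd additive Gaussian pixel noise s.d. (grey levels).
#' @return a validated [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(boundaryNoiseAmplitude = 0, elongationJitter = 0)
#' @export
phantomSpec <- function(imageSize = 256L,
                        zpOuterAxes = c(88, 85),
                        zpThickness = 13,
                        pvsOuterScale = 0.92,
                        ooplasmScale = 0.90,
                        centerOffsetSd = 1.0,
                        rotation = NA_real_,
                        elongationJitter = 0.02,
                        scaleJitter = 0.03,
                        boundaryNoiseAmplitude = 1.2,
                        boundaryNoiseModes = 2:5,
                        intensityLevels = c(background = 190, ooplasm = 95,
                                            pvs = 235, zp = 140),
                        noiseSd = 8) {
  new("PhantomSpec",
      imageSize = as.integer(imageSize),
      zpOuterAxes = as.numeric(zpOuterAxes),
      zpThickness = as.numeric(zpThickness),
      pvsOuterScale = as.numeric(pvsOuterScale),
      ooplasmScale = as.numeric(ooplasmScale),
      centerOffsetSd = as.numeric(centerOffsetSd),
      rotation = as.numeric(rotation),
      elongationJitter = as.numeric(elongationJitter),
      scaleJitter = as.numeric(scaleJitter),
      boundaryNoiseAmplitude = as.numeric(boundaryNoiseAmplitude),
      boundaryNoiseModes = as.integer(boundaryNoiseModes),
      intensityLevels = intensityLevels,
      noiseSd = as.numeric(noiseSd))
}

#' Construct a logistic outcome model for the phantom population
#'
#' The default drivers mirror the feature families that dominate clinical
#' importance rankings: oocyte age (negative slope), ooplasm roundness
#' (positive), ooplasm-vs-PVS area ratio (negative) and cohort size
#' (positive).  The intercept is set so that the default phantom
#' population has a blastocyst prevalence of roughly 40 percent.  With all
#' coefficients zero the prevalence is exactly \code{sigmoid(intercept)}.
#'
#' @param intercept logit-scale intercept.
#' @param coefficients named numeric vector of slopes; names must be
#'   drawn from the latent feature names available to the generator
#'   (see [generateCohortDataset()]).
#' @return an [OutcomeModel-class] object.
#' @export
outcomeModel <- function(intercept = -5.72,
                         coefficients = c(oocyte_age = -0.12,
                                          ooplasm_roundness = 18,
                                          ooplasm_vs_pvs_area_ratio = -10,
                                          n_mii_oocytes = 0.04)) {
  new("OutcomeModel", intercept = as.numeric(intercept),
      coefficients = coefficients)
}

#' Linear predictor and probability of an outcome model
#'
#' @param model an [OutcomeModel-class].
#' @param features data.frame or named list holding every column named in
#'   the model's coefficients.
#' @return numeric vector of probabilities in (0, 1).
#' @export
outcomeProbability <- function(model, features) {
  stopifnot(is(model, "OutcomeModel"))
  feats <- as.data.frame(features, optional = TRUE)
  lp <- rep(model@intercept, nrow(feats))
  if (length(model@coefficients)) {
    miss <- setdiff(names(model@coefficients), names(features))
    if (length(miss))
      stop("outcome model drivers not available: ", paste(miss, collapse = ", "))
    for (nm in names(model@coefficients))
      lp <- lp + model@coefficients[[nm]] * feats[[nm]]
  }
  plogis(lp)
}

## ---- internal geometry sampling -------------------------------------

## Draw per-oocyte geometry under an active RNG.  Returns analytic truth:
## per region centre, semi-axes, shared rotation and Fourier boundary
## perturbation.  Nesting is enforced: the ooplasm (resp. PVS) is shrunk,
## aspect preserved, whenever worst-case boundary noise plus centre offset
## would let it touch its enclosing boundary.
sampleOocyteGeometry <- function(spec) {
  n <- spec@imageSize
  amp <- spec@boundaryNoiseAmplitude
  rot <- if (is.na(spec@rotation)) runif(1, 0, pi) else spec@rotation
  elong <- function() clamp(rnorm(1, 0, spec@elongationJitter),
                            -2.5 * spec@elongationJitter,
                            2.5 * spec@elongationJitter)
  sjit <- function() clamp(rnorm(1, 0, spec@scaleJitter),
                           -2.5 * spec@scaleJitter,
                           2.5 * spec@scaleJitter)
  fourier <- function() {
    if (amp <= 0 || !length(spec@boundaryNoiseModes))
      return(list(modes = integer(), amp = numeric(), phase = numeric()))
    k <- spec@boundaryNoiseModes
    a <- rnorm(length(k), 0, amp / k)
    tot <- sum(abs(a))
    if (tot > 1.5 * amp) a <- a * (1.5 * amp) / tot
    list(modes = k, amp = a, phase = runif(length(k), 0, 2 * pi))
  }
  stretch <- function(ax, e) c(ax[1] * (1 + e), ax[2] / (1 + e))
  ## inner regions inherit their parent's size through the geometric-mean
  ## radius but draw their aspect independently around the spec's base
  ## shape, so region shapes are not artificially collinear
  q0 <- sqrt(spec@zpOuterAxes[1] / spec@zpOuterAxes[2])
  shapeFromRadius <- function(r, e) c(r * q0 * (1 + e), r / (q0 * (1 + e)))

  ctr <- c((n - 1) / 2, (n - 1) / 2)
  zpC <- ctr + rnorm(2, 0, spec@centerOffsetSd)
  zpAx <- stretch(spec@zpOuterAxes, elong())
  zpF <- fourier()

  zpInner <- pmax(zpAx - spec@zpThickness, 1)
  pvsC <- zpC + rnorm(2, 0, spec@centerOffsetSd / 2)
  pvsAx <- shapeFromRadius(sqrt(prod(zpInner)) * spec@pvsOuterScale * (1 + sjit()),
                           elong())
  pvsF <- fourier()
  ## the ZP ring must stay visible: keep the PVS boundary clear of the ZP
  ## outer boundary by the noise budget plus a 1.5 px minimum ring
  gapZp <- 1.5 * amp * 2 + sqrt(sum((pvsC - zpC)^2)) + 1.5
  sP <- min(1, (zpAx[1] - gapZp) / pvsAx[1], (zpAx[2] - gapZp) / pvsAx[2])
  pvsAx <- pvsAx * sP

  ooC <- pvsC + rnorm(2, 0, spec@centerOffsetSd / 2)
  ooAx <- shapeFromRadius(sqrt(prod(pvsAx)) * spec@ooplasmScale * (1 + sjit()),
                          elong())
  ooF <- fourier()
  gapOo <- 1.5 * amp * 2 + sqrt(sum((ooC - pvsC)^2)) + 0.5
  sO <- min(1, (pvsAx[1] - gapOo) / ooAx[1], (pvsAx[2] - gapOo) / ooAx[2])
  ooAx <- ooAx * sO

  mk <- function(center, ax, f) {
    a <- max(ax); b <- min(ax)
    list(center = center, semiAxes = c(a, b), rotation = rot,
         fourier = f,
         area = pi * a * b, perimeter = ellipsePerimeter(a, b),
         majorAxis = 2 * a, minorAxis = 2 * b)
  }
  list(rotation = rot,
       regions = list(ooplasm = mk(ooC, ooAx, ooF),
                      pvs = mk(pvsC, pvsAx, pvsF),
                      zp = mk(zpC, zpAx, zpF)))
}

## membership of pixel centres in one (possibly perturbed) ellipse
regionMask <- function(geomRegion, n, grid = NULL) {
  if (is.null(grid)) grid <- pixelGrid(n)
  cx <- geomRegion$center[1]; cy <- geomRegion$center[2]
  a <- geomRegion$semiAxes[1]; b <- geomRegion$semiAxes[2]
  th <- geomRegion$rotation
  dx <- grid$x - cx; dy <- grid$y - cy
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  rho <- sqrt((u / a)^2 + (v / b)^2)
  f <- geomRegion$fourier
  if (length(f$modes)) {
    theta <- atan2(v / b, u / a)
    bound <- 1
    r0 <- sqrt(a * b)
    for (i in seq_along(f$modes))
      bound <- bound + (f$amp[i] / r0) * cos(f$modes[i] * theta + f$phase[i])
    rho <= bound
  } else rho <= 1
}

pixelGrid <- function(n) {
  xs <- seq_len(n) - 1
  list(x = matrix(xs, n, n, byrow = TRUE),  # column index -> x
       y = matrix(xs, n, n))                # row index -> y
}

#' Rasterize analytic phantom geometry into a label image
#'
#' Regions are painted outer-to-inner (ZP = 3, PVS = 2, ooplasm = 1 over a
#' background of 0), so every pixel carries exactly one class and nesting
#' is guaranteed.
#'
#' @param geometry a geometry-truth object as returned in
#'   \code{generatePhantom()$geometry}.
#' @param imageSize image side in px.
#' @return integer label matrix (rows = y, columns = x).
#' @export
rasterizeGeometry <- function(geometry, imageSize) {
  n <- as.integer(imageSize)
  grid <- pixelGrid(n)
  lab <- matrix(0L, n, n)
  lab[regionMask(geometry$regions$zp, n, grid)] <- REGION_CODES[["zp"]]
  lab[regionMask(geometry$regions$pvs, n, grid)] <- REGION_CODES[["pvs"]]
  lab[regionMask(geometry$regions$ooplasm, n, grid)] <- REGION_CODES[["ooplasm"]]
  lab
}

renderIntensity <- function(label, spec) {
  lv <- spec@intensityLevels
  img <- matrix(lv[["background"]], nrow(label), ncol(label))
  img[label == 1L] <- lv[["ooplasm"]]
  img[label == 2L] <- lv[["pvs"]]
  img[label == 3L] <- lv[["zp"]]
  if (spec@noiseSd > 0)
    img <- img + rnorm(length(img), 0, spec@noiseSd)
  matrix(clamp(round(img), 0, 255), nrow(label))
}

#' Generate a single synthetic oocyte phantom
#'
#' Deterministic for a fixed \code{(spec, seed)} pair: the same call
#' returns bit-identical images, label images and geometry truth.
#'
#' @param spec a [PhantomSpec-class]; validated on entry.
#' @param seed integer seed.
#' @return list with elements \code{image} (numeric matrix, 8-bit grey
#'   levels), \code{label} (integer matrix with codes background = 0,
#'   ooplasm = 1, PVS = 2, ZP = 3) and \code{geometry} (analytic truth:
#'   per-region centre, semi-axes, rotation, area, perimeter and axes of
#'   the boundary ellipse).
#' @examples
#' ph <- generatePhantom(phantomSpec(boundaryNoiseAmplitude = 0), seed = 1)
#' table(ph$label)
#' @export
generatePhantom <- function(spec = phantomSpec(), seed = 1L) {
  validObject(spec)
  withSeed(seed, {
    geom <- sampleOocyteGeometry(spec)
    label <- rasterizeGeometry(geom, spec@imageSize)
    image <- renderIntensity(label, spec)
    list(image = image, label = label, geometry = geom)
  })
}

## latent (analytic) features available as outcome-model drivers
latentFeatures <- function(geom) {
  g <- geom$regions
  ax <- function(r) g[[r]]$semiAxes
  area <- function(r) prod(ax(r)) * pi
  c(ooplasm_roundness = ax("ooplasm")[2] / ax("ooplasm")[1],
    ooplasm_aspect_ratio = ax("ooplasm")[1] / ax("ooplasm")[2],
    ooplasm_vs_pvs_area_ratio = area("ooplasm") / area("pvs"),
    ooplasm_vs_zp_area_ratio = area("ooplasm") / area("zp"),
    ooplasm_vs_zp_major_axis_ratio = ax("ooplasm")[1] / ax("zp")[1],
    pvs_vs_zp_area_ratio = area("pvs") / area("zp"))
}

## default clinical distributions for the phantom population
defaultCohortSizeDistribution <- function(n) {
  ## zero-truncated negative binomial calibrated to mean 6.9, s.d. 4.6
  ## MII oocytes per retrieval cycle
  x <- rnbinom(n, size = 3.33, mu = 6.9)
  pmax(x, 1L)
}

defaultAgeDistribution <- function(n) {
  ## oocyte age (donor-aware), mean 36.0 s.d. 4.5 years, integer ages
  as.integer(round(clamp(rnorm(n, 36, 4.5), 18, 46)))
}

#' Generate a cohort-structured phantom dataset
#'
#' Emulates the structure of a multi-clinic ICSI study: patients attend
#' one or more retrieval cycles; each cycle yields a cohort of MII oocytes
#' whose size is the \code{n_mii_oocytes} clinical feature.  Every oocyte
#' receives phantom geometry, a rasterized label image is measured by the
#' morphometry module, and the binary blastocyst outcome is drawn
#' Bernoulli from \code{outcomeModel} applied to the oocyte's latent
#' (analytic) features.  The latent true probability is retained so the
#' generator's Bayes-optimal AUC can be computed on any subset.
#'
#' The draw is fully deterministic for a fixed seed, and identical whether
#' or not intensity images are kept.
#'
#' @param nPatients number of patients.
#' @param cohortSizeDistribution function(n) returning n positive integer
#'   cohort sizes; default truncated negative binomial, mean 6.9, s.d. 4.6.
#' @param ageDistribution function(n) returning n integer oocyte ages;
#'   default normal mean 36 s.d. 4.5, clamped to 18--46.
#' @param outcomeModel an [OutcomeModel-class].
#' @param seed integer seed.
#' @param spec a [PhantomSpec-class].
#' @param clinics character vector of site labels.
#' @param clinicWeights sampling weights for sites.
#' @param extraCycleRate Poisson rate of additional cycles per patient
#'   (each patient has at least one cycle).
#' @param keepImages keep rendered intensity images (memory-heavy).
#' @param keepLabels keep label images.
#' @return an [OocyteStudy-class].
#' @examples
#' study <- generateCohortDataset(nPatients = 3, seed = 1)
#' head(oocyteData(study))
#' @export
generateCohortDataset <- function(nPatients,
                                  cohortSizeDistribution = defaultCohortSizeDistribution,
                                  ageDistribution = defaultAgeDistribution,
                                  outcomeModel = oomorph::outcomeModel(),
                                  seed = 1L,
                                  spec = phantomSpec(),
                                  clinics = paste0("site_", LETTERS[1:5]),
                                  clinicWeights = c(0.30, 0.25, 0.20, 0.15, 0.10),
                                  extraCycleRate = 0.19,
                                  keepImages = FALSE,
                                  keepLabels = FALSE) {
  validObject(spec)
  validObject(outcomeModel)
  if (nPatients < 1) stop("nPatients must be positive")
  withSeed(seed, {
    clinic <- sample(clinics, nPatients, replace = TRUE, prob = clinicWeights)
    nCycles <- 1L + rpois(nPatients, extraCycleRate)
    patAge <- ageDistribution(nPatients)

    rows <- list(); geoms <- list(); k <- 0L
    for (p in seq_len(nPatients)) {
      for (cy in seq_len(nCycles[p])) {
        m <- cohortSizeDistribution(1L)
        if (!is.finite(m) || m < 1)
          stop("cohortSizeDistribution produced an empty cohort")
        for (o in seq_len(m)) {
          k <- k + 1L
          geom <- sampleOocyteGeometry(spec)
          lf <- c(as.list(latentFeatures(geom)),
                  oocyte_age = patAge[p], n_mii_oocytes = as.integer(m))
          pTrue <- outcomeProbability(outcomeModel, lf)
          rows[[k]] <- data.frame(
            oocyte_id = sprintf("O%05d", k),
            patient_id = sprintf("P%04d", p),
            cycle_id = sprintf("P%04d_C%d", p, cy),
            clinic = clinic[p],
            oocyte_age = patAge[p],
            n_mii_oocytes = as.integer(m),
            true_probability = pTrue,
            true_ooplasm_roundness = lf$ooplasm_roundness,
            true_ooplasm_vs_pvs_area_ratio = lf$ooplasm_vs_pvs_area_ratio,
            true_ooplasm_vs_zp_major_axis_ratio = lf$ooplasm_vs_zp_major_axis_ratio,
            stringsAsFactors = FALSE)
          geoms[[k]] <- geom
        }
      }
    }
    oo <- do.call(rbind, rows)
    oo$outcome <- rbinom(nrow(oo), 1L, oo$true_probability)

    ## rasterize + measure after all stochastic draws, so record-level
    ## reproducibility does not depend on what is kept
    labels <- vector("list", nrow(oo))
    meas <- vector("list", nrow(oo))
    for (i in seq_len(nrow(oo))) {
      lab <- rasterizeGeometry(geoms[[i]], spec@imageSize)
      meas[[i]] <- measureOocyte(lab)
      if (keepLabels || keepImages) labels[[i]] <- lab
    }
    oo <- cbind(oo, do.call(rbind, meas))
    images <- list()
    if (keepImages)
      images <- lapply(seq_len(nrow(oo)), function(i)
        withSeed((as.numeric(seed) + i) %% 2147483647,
                 renderIntensity(labels[[i]], spec)))
    if (!keepLabels) labels <- list()
    rownames(oo) <- oo$oocyte_id
    new("OocyteStudy", oocytes = oo, spec = spec,
        outcomeModel = outcomeModel, seed = as.integer(seed),
        images = images, labels = labels)
  })
}

#' Per-oocyte table of a generated study
#' @param study an [OocyteStudy-class].
#' @return the per-oocyte data.frame.
#' @export
oocyteData <- function(study) {
  stopifnot(is(study, "OocyteStudy"))
  study@oocytes
}

#' @describeIn OocyteStudy-class compact display
#' @param object an OocyteStudy
#' @export
setMethod("show", "OocyteStudy", function(object) {
  oo <- object@oocytes
  cat("OocyteStudy:", nrow(oo), "oocytes,",
      length(unique(oo$patient_id)), "patients,",
      length(unique(oo$cycle_id)), "cycles,",
      length(unique(oo$clinic)), "clinics\n")
  cat("  prevalence:", round(mean(oo$outcome), 3),
      " seed:", object@seed, "\n")
})

#' @describeIn PhantomSpec-class compact display
#' @param object a PhantomSpec
#' @export
setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %dpx image, ZP axes (%.1f, %.1f), thickness %.1f\n",
              object@imageSize, object@zpOuterAxes[1], object@zpOuterAxes[2],
              object@zpThickness))
  cat(sprintf("  scales pvs %.2f ooplasm %.2f | jitter elong %.3f scale %.3f | boundary amp %.1fpx | noise sd %.1f\n",
              object@pvsOuterScale, object@ooplasmScale,
              object@elongationJitter, object@scaleJitter,
              object@boundaryNoiseAmplitude, object@noiseSd))
})
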