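## Label-image handling, per-class IoU evaluation and a classical
## baseline segmenter adequate for intensity-banded phantom images.

#' Validate a four-class oocyte label image
#'
#' @param labelImage matrix expected to carry only the codes
#'   background = 0, ooplasm = 1, PVS = 2, ZP = 3.
#' @param requireAllClasses additionally require codes 1--3 to be present
#'   (a "valid oocyte" image).
#' @return the label image, invisibly, as an integer matrix.
#' @export
validateLabelImage <- function(labelImage, requireAllClasses = FALSE) {
  if (!is.matrix(labelImage))
    stop("label image must be a matrix")
  vals <- unique(as.vector(labelImage))
  if (!all(vals %in% 0:3))
    stop("label image contains codes outside {0, 1, 2, 3}: ",
         paste(utils::head(setdiff(vals, 0:3), 5), collapse = ", "))
  if (requireAllClasses && !all(1:3 %in% vals))
    stop("label image is missing one of the oocyte classes 1..3")
  invisible(matrix(as.integer(labelImage), nrow(labelImage)))
}

#' Per-class intersection over union
#'
#' \eqn{IoU = TP / (TP + FP + FN)}: the overlap of the binary masks of
#' one class between a ground-truth and a predicted label image, i.e.
#' \eqn{|A \cap B| / |A \cup B|}.  Symmetric in its two arguments.
#'
#' @param yLabel,yPred label matrices of identical shape.
#' @param classCode class to evaluate (1 = ooplasm, 2 = PVS, 3 = ZP).
#' @return IoU in [0, 1].  If the class is absent from both images the
#'   value is undefined and an error is raised rather than silently
#'   returning 0.
#' @examples
#' a <- matrix(0L, 4, 4); a[2:3, 2:3] <- 1L
#' iou(a, a, 1)  # 1
#' @export
iou <- function(yLabel, yPred, classCode) {
  if (!identical(dim(yLabel), dim(yPred)))
    stop("label and prediction must have the same shape")
  if (!classCode %in% 1:3)
    stop("classCode must be 1 (ooplasm), 2 (PVS) or 3 (ZP)")
  a <- yLabel == classCode
  b <- yPred == classCode
  uni <- sum(a | b)
  if (uni == 0)
    stop(sprintf("class %d absent from both images: IoU undefined", classCode))
  sum(a & b) / uni
}

#' Evaluate segmentations over a set of image pairs
#'
#' Computes the per-class IoU for every (ground truth, prediction) pair
#' and summarises mean and standard deviation per class, the per-class
#' average reported for segmentation models.  Images where a class is
#' absent from both truth and prediction are excluded from that class's
#' summary with a warning (all-region MII oocytes carry every class).
#'
#' @param pairs list of \code{list(label = , pred = )} pairs.
#' @param classCodes classes to evaluate, default 1:3.
#' @return a [SegmentationReport-class].
#' @export
evaluateSegmentation <- function(pairs, classCodes = 1:3) {
  if (!length(pairs)) stop("pairs must be a non-empty list")
  rows <- list(); k <- 0L
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    if (!identical(dim(p$label), dim(p$pred)))
      stop(sprintf("shape mismatch in pair %d: %s vs %s", i,
                   paste(dim(p$label), collapse = "x"),
                   paste(dim(p$pred), collapse = "x")))
    for (cls in classCodes) {
      if (!any(p$label == cls) && !any(p$pred == cls)) {
        warning(sprintf("pair %d: class %d absent from truth and prediction; excluded", i, cls))
        next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(image = i, class = cls,
                              iou = iou(p$label, p$pred, cls))
    }
  }
  perImage <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(sort(unique(perImage$class)), function(cls) {
    v <- perImage$iou[perImage$class == cls]
    data.frame(class = cls, mean = mean(v),
               sd = if (length(v) > 1) sd(v) else 0, n = length(v))
  }))
  new("SegmentationReport", perImage = perImage, summary = summ)
}

#' @describeIn SegmentationReport-class compact display
#' @param object a SegmentationReport
#' @export
setMethod("show", "SegmentationReport", function(object) {
  cat("SegmentationReport over",
      length(unique(object@perImage$image)), "images\n")
  cls <- c("1" = "ooplasm", "2" = "pvs", "3" = "zp")
  for (i in seq_len(nrow(object@summary)))
    cat(sprintf("  %-8s IoU %.4f +/- %.4f (n=%d)\n",
                cls[as.character(object@summary$class[i])],
                object@summary$mean[i], object@summary$sd[i],
                object@summary$n[i]))
})

largestComponent <- function(mask) {
  lbl <- EBImage::bwlabel(mask * 1)
  if (max(lbl) == 0) return(mask & FALSE)
  tab <- tabulate(lbl[lbl > 0])
  lbl == which.max(tab)
}

fillHoles <- function(mask) {
  EBImage::fillHull(mask * 1) > 0
}

#' Classical baseline segmentation of a phantom oocyte image
#'
#' A desk-scale stand-in for a learned multi-class segmenter, adequate for
#' intensity-banded phantoms: light median denoising, four-mode intensity
#' clustering (quantile-initialised k-means), then topological repair that
#' enforces one connected region per class and restores the anatomical
#' nesting (ooplasm inside PVS inside ZP).  The class of each intensity
#' mode is identified from topology alone: the background is the mode
#' that dominates the image border, the oocyte is the largest filled
#' non-background component, and the remaining modes are ranked by the
#' area of their filled largest blob inside the oocyte — these are nested
#' (ooplasm disc inside the filled PVS boundary inside the whole oocyte),
#' so the smallest is the ooplasm and the middle one the PVS.
#'
#' @param image numeric matrix of grey values (0--255 or 0--1).
#' @param medianRadius number of 3x3 median-filter denoising passes.
#' @param minModeSeparation minimum grey-level range (8-bit) below which
#'   the image is declared unsegmentable.
#' @return an integer label matrix with codes 0--3.
#' @export
segmentBaseline <- function(image, medianRadius = 1L, minModeSeparation = 25) {
  if (!is.matrix(image)) stop("image must be a matrix")
  img <- image
  if (max(img) > 1) img <- img / 255
  rng <- diff(range(img))
  if (rng * 255 < minModeSeparation)
    stop("segmentation failure: fewer than 4 distinguishable intensity modes")
  for (pass in seq_len(medianRadius))
    img <- median3x3Cpp(img)
  v <- as.vector(img)
  ## deterministic initialisation: evenly spaced centres across the
  ## intensity range (quantile seeds collapse onto a dominant background
  ## mode in noise-free images)
  centers <- matrix(seq(min(v), max(v), length.out = 4), ncol = 1)
  km <- suppressWarnings(kmeans(v, centers = centers, iter.max = 30))
  if (length(unique(km$cluster)) < 4)
    stop("segmentation failure: fewer than 4 distinguishable intensity modes")
  cl <- matrix(km$cluster, nrow(img))

  border <- c(cl[1, ], cl[nrow(cl), ], cl[, 1], cl[, ncol(cl)])
  bg <- as.integer(names(which.max(table(border))))

  oocyte <- fillHoles(largestComponent(cl != bg))
  if (sum(oocyte) < 200)
    stop("segmentation failure: no oocyte-sized foreground object")

  inner <- sort(setdiff(unique(as.vector(cl[oocyte])), bg))
  if (length(inner) < 3)
    stop("segmentation failure: fewer than 4 distinguishable intensity modes")
  ## the filled largest blob of each remaining intensity mode is nested:
  ## ooplasm disc inside the filled PVS boundary inside the whole oocyte;
  ## sorting the filled areas therefore identifies the classes without
  ## any intensity-order assumption
  filled <- lapply(inner, function(cc)
    fillHoles(largestComponent(cl == cc & oocyte)))
  areas <- vapply(filled, sum, numeric(1))
  ord <- order(areas)
  ooplasm <- filled[[ord[1]]]
  pvsFilled <- filled[[ord[2]]]
  ## repair nesting: ooplasm subset of pvsFilled subset of oocyte
  pvsFilled <- fillHoles(pvsFilled | ooplasm) & oocyte
  ooplasm <- ooplasm & pvsFilled

  out <- matrix(0L, nrow(img), ncol(img))
  out[oocyte] <- 3L
  out[pvsFilled] <- 2L
  out[ooplasm] <- 1L
  if (!all(1:3 %in% out))
    stop("segmentation failure: could not recover all three oocyte classes")
  out
}

## ---- label image I/O -------------------------------------------------

#' Read / write label images as 8-bit PNG
#'
#' Label PNGs store the raw class codes 0--3 as 8-bit grey values.
#'
#' @param path file path.
#' @return \code{readLabelImage} returns an integer label matrix.
#' @export
readLabelImage <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  validateLabelImage(matrix(as.integer(round(m * 255)), nrow(m)))
  matrix(as.integer(round(m * 255)), nrow(m))
}

#' @rdname readLabelImage
#' @param labelImage integer label matrix with codes 0--3.
#' @export
writeLabelImage <- function(labelImage, path) {
  validateLabelImage(labelImage)
  png::writePNG(labelImage / 255, path)
  invisible(path)
}

#' Read / write greyscale intensity images as 8-bit PNG
#' @param path file path.
#' @return \code{readGrayImage} returns a numeric matrix in 0--255.
#' @export
readGrayImage <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(m * 255, nrow(m))
}

#' @rdname readGrayImage
#' @param image numeric matrix in 0--255.
#' @export
writeGrayImage <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}
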