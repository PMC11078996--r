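## Morphometry of oocyte regions from label images.
##
## Measurements follow the filled-outer-contour convention: the geometry
## of a region is that of the area enclosed by its outer boundary, so the
## PVS measurement covers ooplasm plus PVS annulus and the ZP measurement
## the whole oocyte.  Between-region ratios of such measurements lie in
## (0, 1], which is the scale on which clinical morphometric ratios are
## reported.
##
## Contours are extracted at sub-pixel precision (marching-squares
## iso-lines at level 0.5 between label codes) and lightly smoothed with a
## circular moving average before measuring: raw pixel-edge polygons
## systematically overestimate the perimeter and depress circularity.

#' Construct a RegionGeometry from analytic measurements
#'
#' Direct constructor for analytically known shapes (exact circles,
#' ellipses, polygons); [regionGeometry()] measures a region from a label
#' image instead.
#'
#' @param region region name; free-form for analytic constructions.
#' @param area enclosed area A.
#' @param perimeter boundary length Lp.
#' @param majorAxis,minorAxis best-fit ellipse axes Lmaj, Lmin.
#' @param hullArea convex hull area Ahull.
#' @return a validated [RegionGeometry-class].
#' @examples
#' circ <- RegionGeometry("custom", area = pi * 50^2, perimeter = 2 * pi * 50,
#'                        majorAxis = 100, minorAxis = 100, hullArea = pi * 50^2)
#' shapeDescriptors(circ)
#' @export
RegionGeometry <- function(region, area, perimeter, majorAxis, minorAxis,
                           hullArea) {
  new("RegionGeometry", region = as.character(region), area = as.numeric(area),
      perimeter = as.numeric(perimeter), majorAxis = as.numeric(majorAxis),
      minorAxis = as.numeric(minorAxis), hullArea = as.numeric(hullArea))
}

#' @describeIn RegionGeometry-class compact display
#' @param object a RegionGeometry
#' @export
setMethod("show", "RegionGeometry", function(object) {
  cat(sprintf("RegionGeometry [%s]: A=%.1f Lp=%.1f Lmaj=%.1f Lmin=%.1f Ahull=%.1f\n",
              object@region, object@area, object@perimeter,
              object@majorAxis, object@minorAxis, object@hullArea))
})

## extract the dominant closed outer contour of a binary mask at sub-pixel
## precision; the mask is cropped to its bounding box first for speed
maskOuterContour <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(min(idx[, 1]) - 2L, 1L); r1 <- min(max(idx[, 1]) + 2L, nrow(mask))
  c0 <- max(min(idx[, 2]) - 2L, 1L); c1 <- min(max(idx[, 2]) + 2L, ncol(mask))
  sub <- mask[r0:r1, c0:c1] * 1.0
  ## contourLines takes z[i, j] at x[i], y[j]; our rows are y and columns x
  cl <- contourLines(x = (r0:r1) - 1, y = (c0:c1) - 1, z = sub, levels = 0.5)
  if (!length(cl)) stop("no contour found for region mask")
  len <- vapply(cl, function(co) length(co$x), numeric(1))
  co <- cl[[which.max(len)]]
  ## returned $x follows rows (our y); relabel into (x, y)
  x <- co$y; y <- co$x
  if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  list(x = x, y = y)
}

## circular moving-average smoothing of a closed polygon
smoothClosedPolygon <- function(x, y, window = 9L) {
  n <- length(x)
  w <- min(window, if (n %% 2L == 0L) n - 1L else n)
  if (w < 3L) return(list(x = x, y = y))
  k <- rep(1 / w, w)
  circ <- function(z) {
    zz <- c(z[(n - w + 1):n], z, z[1:w])
    f <- stats::filter(zz, k, sides = 2)
    as.numeric(f[(w + 1):(w + n)])
  }
  list(x = circ(x), y = circ(y))
}

## direct least-squares ellipse fit (conic with 4AC - B^2 > 0 enforced),
## numerically stabilised by centring and scaling the points
fitEllipse <- function(x, y) {
  mx <- mean(x); my <- mean(y); s <- max(sd(x), sd(y))
  if (!is.finite(s) || s <= 0) stop("degenerate contour: cannot fit ellipse")
  xs <- (x - mx) / s; ys <- (y - my) / s
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("ellipse fit failed: no admissible conic")
  a1 <- vecs[, ok[1]]
  par <- c(a1, as.numeric(Tm %*% a1))
  A <- par[1]; B <- par[2]; C <- par[3]; D <- par[4]; E <- par[5]; F <- par[6]
  ## undo the normalisation
  A2 <- A / s^2; B2 <- B / s^2; C2 <- C / s^2
  D2c <- D / s - 2 * A * mx / s^2 - B * my / s^2
  E2c <- E / s - 2 * C * my / s^2 - B * mx / s^2
  F2 <- F + A * mx^2 / s^2 + B * mx * my / s^2 + C * my^2 / s^2 -
    D * mx / s - E * my / s
  A <- A2; B <- B2; C <- C2; D <- D2c; E <- E2c; F <- F2
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  tmp <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + tmp)) / den
  ax2 <- -sqrt(num * (A + C - tmp)) / den
  if (!is.finite(ax1) || !is.finite(ax2) || ax1 <= 0 || ax2 <= 0)
    stop("ellipse fit failed: degenerate axes")
  list(center = c(cx, cy),
       semiMajor = max(ax1, ax2), semiMinor = min(ax1, ax2),
       angle = atan2(C - A - tmp, B))
}

## binary mask of one region under the filled-outer-contour convention
regionFilledMask <- function(labelImage, region) {
  code <- REGION_CODES[[region]]
  if (is.null(code) || code == 0L)
    stop("region must be one of ", paste(REGIONS, collapse = ", "))
  labelImage >= 1L & labelImage <= code
}

#' Measure one oocyte region from a label image
#'
#' Computes the standard filled-outer-contour cell-morphometry
#' measurements: area A (sub-pixel polygon area), perimeter Lp (smoothed
#' contour arc length), best-fit-ellipse axes Lmaj and Lmin (direct
#' least-squares conic fit to the contour polygon) and convex-hull area
#' Ahull.
#'
#' @param labelImage integer label matrix with codes background = 0,
#'   ooplasm = 1, PVS = 2, ZP = 3.
#' @param region one of \code{"ooplasm"}, \code{"pvs"}, \code{"zp"}.
#' @param minPixels minimum region pixel count below which measurement is
#'   refused (descriptor noise dominates for tiny masks).
#' @return a [RegionGeometry-class].
#' @examples
#' ph <- generatePhantom(phantomSpec(boundaryNoiseAmplitude = 0,
#'                                   elongationJitter = 0, scaleJitter = 0,
#'                                   centerOffsetSd = 0, rotation = 0), seed = 1)
#' regionGeometry(ph$label, "ooplasm")
#' @export
regionGeometry <- function(labelImage, region = c("ooplasm", "pvs", "zp"),
                           minPixels = 50L) {
  region <- match.arg(region)
  validateLabelImage(labelImage)
  mask <- regionFilledMask(labelImage, region)
  npx <- sum(mask)
  if (npx < minPixels)
    stop(sprintf("region '%s' absent or below the minimum size of %d px (found %d)",
                 region, minPixels, npx))
  co <- maskOuterContour(mask)
  po <- smoothClosedPolygon(co$x, co$y)
  area <- polygonArea(po$x, po$y)
  per <- polygonPerimeter(po$x, po$y)
  fit <- fitEllipse(po$x, po$y)
  h <- chull(po$x, po$y)
  hull <- polygonArea(po$x[h], po$y[h])
  RegionGeometry(region, area = area, perimeter = per,
                 majorAxis = 2 * fit$semiMajor, minorAxis = 2 * fit$semiMinor,
                 hullArea = max(hull, area))
}

#' Dimensionless shape descriptors of a region
#'
#' Applies the four standard cell-shape formulas: aspect ratio
#' \eqn{R_A = L_{maj}/L_{min}}, circularity \eqn{C = 4\pi A / L_p^2},
#' roundness \eqn{R = 4A/(\pi L_{maj}^2)} and solidity
#' \eqn{S = A/A_{hull}}.  A perfect circle has C = R = RA = 1 and any
#' convex region has S = 1.  Values are reported without clamping: raster
#' overshoot slightly above 1 is possible and covered by the stated
#' tolerances in the test-suite, not hidden.
#'
#' @param geom a [RegionGeometry-class].
#' @return named numeric vector with elements \code{aspect_ratio},
#'   \code{circularity}, \code{roundness}, \code{solidity}.
#' @examples
#' shapeDescriptors(RegionGeometry("custom", pi * 4, 4 * pi, 4, 4, pi * 4))
#' @export
shapeDescriptors <- function(geom) {
  stopifnot(is(geom, "RegionGeometry"))
  if (geom@minorAxis <= 0 || geom@perimeter <= 0)
    stop("zero minor axis or perimeter: descriptors undefined")
  c(aspect_ratio = geom@majorAxis / geom@minorAxis,
    circularity = 4 * pi * geom@area / geom@perimeter^2,
    roundness = 4 * geom@area / (pi * geom@majorAxis^2),
    solidity = geom@area / geom@hullArea)
}

#' Between-region ratio ("relative") features of one oocyte
#'
#' For each region pair (ooplasm/PVS, ooplasm/ZP, PVS/ZP) and each measure
#' (major axis, minor axis, perimeter, area) the ratio inner/outer is
#' returned; under the filled-outer-contour convention these lie in
#' (0, 1].  The convex-hull area is only used for solidity and is never
#' compared between regions.
#'
#' @param geoms named list with elements \code{ooplasm}, \code{pvs},
#'   \code{zp}, each a [RegionGeometry-class].
#' @return named numeric vector of 12 ratios, e.g.
#'   \code{ooplasm_vs_pvs_area_ratio}.
#' @export
relativeFeatures <- function(geoms) {
  if (!all(REGIONS %in% names(geoms)))
    stop("geoms must contain ooplasm, pvs and zp measurements")
  get <- function(g, m) switch(m,
    major_axis = g@majorAxis, minor_axis = g@minorAxis,
    perimeter = g@perimeter, area = g@area)
  out <- numeric(0)
  for (pair in REGION_PAIRS) {
    parts <- strsplit(pair, "_vs_")[[1]]
    for (m in MEASURES) {
      val <- get(geoms[[parts[1]]], m) / get(geoms[[parts[2]]], m)
      out[paste0(pair, "_", m, "_ratio")] <- val
    }
  }
  out
}

#' Measure all three regions of one oocyte
#'
#' @param labelImage integer label matrix.
#' @param minPixels minimum region size forwarded to [regionGeometry()].
#' @return one-row data.frame with columns
#'   \code{<region>_<area|perimeter|major_axis|minor_axis|hull_area>}.
#' @export
measureOocyte <- function(labelImage, minPixels = 50L) {
  out <- list()
  for (r in REGIONS) {
    g <- regionGeometry(labelImage, r, minPixels = minPixels)
    out[[paste0(r, "_area")]] <- g@area
    out[[paste0(r, "_perimeter")]] <- g@perimeter
    out[[paste0(r, "_major_axis")]] <- g@majorAxis
    out[[paste0(r, "_minor_axis")]] <- g@minorAxis
    out[[paste0(r, "_hull_area")]] <- g@hullArea
  }
  as.data.frame(out)
}
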