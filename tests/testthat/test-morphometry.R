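test_that("raster measurements match analytic circle and ellipse values", {
  # circle of radius 50: both axes within 1% of 100
  lab <- rasterEllipseLabel(50, 50)
  g <- regionGeometry(lab, "ooplasm")
  expect_equal(g@majorAxis, 100, tolerance = 0.01)
  expect_equal(g@minorAxis, 100, tolerance = 0.01)
  # ellipse (60, 50): area within 1.5% of pi*60*50 = 9424.8
  g2 <- regionGeometry(rasterEllipseLabel(60, 50), "ooplasm")
  expect_equal(g2@area, pi * 60 * 50, tolerance = 0.015)
  # a parameterised sweep of axes and rotations against analytic truth
  cases <- list(c(60, 50, 0), c(60, 50, 0.5), c(88, 85, 1.1),
                c(40, 24, 2.2), c(70, 68, 0.9))
  for (cs in cases) {
    a <- cs[1]; b <- cs[2]; th <- cs[3]
    g <- regionGeometry(rasterEllipseLabel(a, b, th), "ooplasm")
    expect_equal(g@area, pi * a * b, tolerance = 0.015)
    expect_equal(g@perimeter, oomorph:::ellipsePerimeter(a, b),
                 tolerance = 0.02)
    expect_equal(g@majorAxis, 2 * a, tolerance = 0.01)
    expect_equal(g@minorAxis, 2 * b, tolerance = 0.01)
    # ellipses are convex: hull area equals area within raster tolerance
    expect_equal(g@hullArea, g@area, tolerance = 0.005)
  }
})

test_that("shape descriptors apply the defining formulas exactly", {
  r <- 37
  circ <- RegionGeometry("custom", area = pi * r^2, perimeter = 2 * pi * r,
                         majorAxis = 2 * r, minorAxis = 2 * r,
                         hullArea = pi * r^2)
  d <- shapeDescriptors(circ)
  expect_equal(unname(d["circularity"]), 1, tolerance = 1e-12)
  expect_equal(unname(d["roundness"]), 1, tolerance = 1e-12)
  expect_identical(unname(d["aspect_ratio"]), 1)
  expect_identical(unname(d["solidity"]), 1)
  # ellipse with Lmaj = 2 Lmin has aspect ratio exactly 2
  ell <- RegionGeometry("custom", area = pi * 40 * 20,
                        perimeter = oomorph:::ellipsePerimeter(40, 20),
                        majorAxis = 80, minorAxis = 40,
                        hullArea = pi * 40 * 20)
  expect_equal(unname(shapeDescriptors(ell)["aspect_ratio"]), 2)
  expect_error(shapeDescriptors(RegionGeometry("x", 1, 1, 1, 1, 1)), NA)
})

test_that("solidity of a notched square matches the exact polygon oracle", {
  # 100x100 square with a 20x20 notch: A = 9600, hull = 10000, S = 0.96
  lab <- matrix(0L, 160, 160)
  lab[30:129, 30:129] <- 1L
  lab[30:49, 70:89] <- 0L
  g <- regionGeometry(lab, "ooplasm")
  expect_equal(unname(shapeDescriptors(g)["solidity"]), 9600 / 10000,
               tolerance = 0.01)
  # convex square: solidity 1 within raster tolerance
  sq <- matrix(0L, 160, 160); sq[30:129, 30:129] <- 1L
  gs <- regionGeometry(sq, "ooplasm")
  expect_equal(unname(shapeDescriptors(gs)["solidity"]), 1, tolerance = 0.005)
})

test_that("relative features follow analytic ratios and exclude hull area", {
  mk <- function(a, b) RegionGeometry("custom", area = pi * a * b,
                                      perimeter = oomorph:::ellipsePerimeter(a, b),
                                      majorAxis = 2 * a, minorAxis = 2 * b,
                                      hullArea = pi * a * b)
  same <- list(ooplasm = mk(50, 45), pvs = mk(50, 45), zp = mk(50, 45))
  expect_true(all(relativeFeatures(same) == 1))
  geoms <- list(ooplasm = mk(55, 50), pvs = mk(60, 55), zp = mk(70, 65))
  rf <- relativeFeatures(geoms)
  expect_equal(unname(rf["ooplasm_vs_pvs_area_ratio"]), 2750 / 3300)
  expect_equal(unname(rf["ooplasm_vs_pvs_major_axis_ratio"]), 55 / 60)
  expect_length(rf, 12)
  expect_false(any(grepl("hull", names(rf))))
  expect_error(relativeFeatures(geoms[1:2]), "must contain")
})

test_that("phantom population recovers the configured axis-ratio mean", {
  study <- generateCohortDataset(75, seed = 7)
  oo <- oocyteData(study)
  expect_gte(nrow(oo), 400)
  ratio <- oo$ooplasm_major_axis / oo$zp_major_axis
  expect_lt(abs(mean(ratio) - 0.70), 0.02)
})

test_that("descriptors are scale and rotation invariant within tolerance", {
  base <- zeroJitterSpec(imageSize = 256L, rotation = 0.7)
  double <- phantomSpec(imageSize = 512L, zpOuterAxes = c(176, 170),
                        zpThickness = 26, boundaryNoiseAmplitude = 0,
                        elongationJitter = 0, scaleJitter = 0,
                        centerOffsetSd = 0, rotation = 0.7, noiseSd = 0)
  m1 <- measureOocyte(generatePhantom(base, seed = 1)$label)
  m2 <- measureOocyte(generatePhantom(double, seed = 1)$label)
  for (r in c("ooplasm", "pvs", "zp")) {
    d1 <- shapeDescriptors(oomorph:::geometryFromRow(m1, r))
    d2 <- shapeDescriptors(oomorph:::geometryFromRow(m2, r))
    expect_equal(d1, d2, tolerance = 0.01)
    # dimensionless ratios: 2x resolution leaves them unchanged
    expect_equal(m1[[paste0(r, "_area")]] / m1$zp_area,
                 m2[[paste0(r, "_area")]] / m2$zp_area, tolerance = 0.005)
  }
  for (rot in c(0, 1.1, 2.6)) {
    m <- measureOocyte(generatePhantom(zeroJitterSpec(rotation = rot),
                                       seed = 1)$label)
    d <- shapeDescriptors(oomorph:::geometryFromRow(m, "ooplasm"))
    dref <- shapeDescriptors(oomorph:::geometryFromRow(m1, "ooplasm"))
    expect_equal(d, dref, tolerance = 0.01)
  }
})

test_that("nested regions order their ratios monotonically", {
  for (s in c(2, 13)) {
    m <- measureOocyte(generatePhantom(phantomSpec(), seed = s)$label)
    geoms <- lapply(c(ooplasm = "ooplasm", pvs = "pvs", zp = "zp"),
                    function(r) oomorph:::geometryFromRow(m, r))
    rf <- relativeFeatures(geoms)
    for (meas in c("major_axis", "minor_axis", "perimeter", "area"))
      expect_lte(rf[[paste0("ooplasm_vs_zp_", meas, "_ratio")]],
                 rf[[paste0("ooplasm_vs_pvs_", meas, "_ratio")]])
  }
})

test_that("tiny or absent regions are refused", {
  lab <- matrix(0L, 64, 64)
  expect_error(regionGeometry(lab, "ooplasm"), "absent or below")
  lab[30:31, 30:31] <- 1L
  expect_error(regionGeometry(lab, "ooplasm"), "minimum size")
})
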