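test_that("cohort algebra matches hand arithmetic", {
  v <- c(0.8, 0.85, 0.9); coh <- c("a", "a", "a")
  expect_equal(cohortAverage(v, coh), rep(0.85, 3))
  expect_equal(cohortRelative(v, coh), c(-0.05, 0, 0.05))
  expect_equal(sum(cohortRelative(v, coh)), 0)
  expect_equal(cohortAverage(0.7, "x"), 0.7)
  expect_equal(cohortRelative(0.7, "x"), 0)
  withr::with_seed(9, {
    vals <- runif(20); g <- rep(c("a", "b"), 10)
    expect_equal(unique(cohortAverage(vals, g)[g == "a"]),
                 sum(vals[g == "a"]) / 20 * 2)
  })
})

test_that("the default feature enumeration is the documented 50 columns", {
  sch <- oomorph:::featureSchemaTable()
  expect_equal(nrow(sch), 50)
  expect_equal(as.vector(table(sch$group)[c("ooplasm", "pvs", "zp",
                                            "relative", "cohort_avg",
                                            "cohort_rel", "clinical")]),
               c(4, 4, 4, 12, 12, 12, 2))
  expect_setequal(sch$column[sch$group == "clinical"],
                  c("oocyte_age", "n_mii_oocytes"))
  # no absolute pixel-valued column enters the model input
  nonclin <- sch$column[sch$group != "clinical"]
  expect_true(all(grepl("ratio|circularity|roundness|solidity", nonclin)))
})

test_that("a two-oocyte cohort reproduces hand-computed features", {
  mkrow <- function(id, a, b, scale1, scale2, age, out) {
    # analytic nested ellipses: ooplasm (a*s1*s2, b*s1*s2), pvs (a*s1, b*s1), zp (a, b)
    ax <- list(zp = c(a, b), pvs = c(a, b) * scale1,
               ooplasm = c(a, b) * scale1 * scale2)
    row <- data.frame(oocyte_id = id, patient_id = "P1", cycle_id = "C1",
                      clinic = "s", oocyte_age = age, n_mii_oocytes = 2L,
                      outcome = out)
    for (r in names(ax)) {
      row[[paste0(r, "_area")]] <- pi * prod(ax[[r]])
      row[[paste0(r, "_perimeter")]] <- oomorph:::ellipsePerimeter(ax[[r]][1], ax[[r]][2])
      row[[paste0(r, "_major_axis")]] <- 2 * ax[[r]][1]
      row[[paste0(r, "_minor_axis")]] <- 2 * ax[[r]][2]
      row[[paste0(r, "_hull_area")]] <- pi * prod(ax[[r]])
    }
    row
  }
  tab <- rbind(mkrow("O1", 80, 76, 0.9, 0.92, 35, 1),
               mkrow("O2", 82, 70, 0.88, 0.95, 35, 0))
  fs <- assembleFeatureTable(tab)
  F <- featureMatrix(fs)
  expect_equal(ncol(F), 50)
  # spreadsheet-style checks on oocyte O1
  expect_equal(F["O1", "zp_aspect_ratio"], 80 / 76)
  expect_equal(F["O1", "ooplasm_solidity"], 1)
  expect_equal(F["O1", "zp_roundness"], 4 * pi * 80 * 76 / (pi * 160^2))
  expect_equal(F["O1", "ooplasm_vs_pvs_area_ratio"], 0.92^2)
  expect_equal(F["O1", "ooplasm_vs_zp_major_axis_ratio"], 0.9 * 0.92)
  expect_equal(F["O1", "pvs_vs_zp_perimeter_ratio"],
               oomorph:::ellipsePerimeter(72, 68.4) / oomorph:::ellipsePerimeter(80, 76))
  # cohort average over the two oocytes, and signed deviations
  avg <- (0.92^2 + 0.95^2) / 2
  expect_equal(F["O1", "cohort_avg_ooplasm_vs_pvs_area_ratio"], avg)
  expect_equal(F["O1", "cohort_rel_ooplasm_vs_pvs_area_ratio"], 0.92^2 - avg)
  expect_equal(F["O2", "cohort_rel_ooplasm_vs_pvs_area_ratio"], 0.95^2 - avg)
  expect_equal(F["O1", "oocyte_age"], 35)
  expect_equal(F["O1", "n_mii_oocytes"], 2)
})

test_that("cohort-relative columns sum to zero within every cohort", {
  fs <- assembleFeatureTable(generateCohortDataset(12, seed = 4))
  sch <- featureSchema(fs)
  for (cc in sch$column[sch$group == "cohort_rel"]) {
    sums <- tapply(fs@features[[cc]], sampleInfo(fs)$cycle_id, sum)
    expect_lt(max(abs(sums)), 1e-12)
  }
})

test_that("group dropping removes exactly the tagged and involved columns", {
  study <- generateCohortDataset(6, seed = 2)
  full <- assembleFeatureTable(study)
  red <- dropFeatureGroups(full, "zp")
  gone <- setdiff(colnames(featureMatrix(full)), colnames(featureMatrix(red)))
  expect_equal(length(gone), 28)  # 4 descriptors + 8 relative + 16 cohort
  expect_true(all(grepl("zp", gone)))
  expect_false(any(grepl("zp", colnames(featureMatrix(red)))))
  noCohort <- dropFeatureGroups(full, "cohort")
  expect_equal(ncol(featureMatrix(noCohort)), 26)
  noClin <- dropFeatureGroups(full, "clinical")
  expect_false("oocyte_age" %in% colnames(featureMatrix(noClin)))
  expect_error(dropFeatureGroups(full, "nonsense"), "unknown feature groups")
  expect_error(dropFeatureGroups(full, c("ooplasm", "pvs", "zp", "clinical")),
               "cannot drop every")
})

test_that("rows with incomplete geometry are rejected with a reason", {
  study <- generateCohortDataset(5, seed = 8)
  oo <- oocyteData(study)
  oo$ooplasm_area[2] <- NA
  expect_message(fs <- assembleFeatureTable(oo), "rejected")
  expect_equal(nrow(featureMatrix(fs)), nrow(oo) - 1)
  expect_false(anyNA(featureMatrix(fs)))
})

test_that("Welch screening surfaces the generator's outcome drivers", {
  om <- outcomeModel(intercept = -46.5,
                     coefficients = c(oocyte_age = -0.30, ooplasm_roundness = 60))
  study <- generateCohortDataset(60, outcomeModel = om, seed = 11)
  fs <- assembleFeatureTable(study)
  scr <- welchScreen(fs)
  expect_lte(which(scr$feature == "oocyte_age"), 15)
  expect_lte(which(scr$feature == "ooplasm_roundness"), 15)
  expect_lt(scr$p[scr$feature == "ooplasm_roundness"], 0.01)
})
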