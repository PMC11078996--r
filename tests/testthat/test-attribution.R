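test_that("attributions match the exhaustive-coalition oracle", {
  toy <- fitToyBooster(n = 300, p = 6)
  refs <- toy$X[1:16, , drop = FALSE]
  for (i in c(20, 101, 250)) {
    ex <- explainSample(toy$model, toy$X[i, ], refs)
    phiB <- shapleyBruteForce(toy$model@booster, toy$X[i, ], refs)
    expect_lt(max(abs(ex@attributions - phiB)), 1e-6)
  }
})

test_that("local accuracy holds on every sample and matches the booster", {
  toy <- fitToyBooster(n = 400, p = 8, beta = c(1.5, -1, 0.5, 0.5, 0, 0, 0, 0),
                       seed = 7)
  refs <- toy$X[1:40, ]
  margins <- predict(toy$model@booster, xgboost::xgb.DMatrix(toy$X),
                     outputmargin = TRUE)
  for (i in seq(1, 400, by = 23)) {
    ex <- explainSample(toy$model, toy$X[i, ], refs, rowId = i)
    expect_lt(abs(ex@baseValue + sum(ex@attributions) - ex@fx), 1e-6)
    expect_lt(abs(ex@fx - margins[i]), 1e-5)
    expect_identical(ex@probability, plogis(ex@fx))
  }
})

test_that("stump ensembles attribute each feature its own marginal effect", {
  # with depth-1 trees the model is additive, so the interventional
  # Shapley value of feature j is f_j(x_j) minus its reference mean;
  # equivalently the mean prediction change when x_j replaces ref_j
  toy <- fitToyBooster(n = 500, p = 4, beta = c(2, -1, 0.7, 0), seed = 5,
                       max_depth = 1, nrounds = 60)
  refs <- toy$X[1:30, ]
  x <- toy$X[77, ]
  ex <- explainSample(toy$model, x, refs)
  for (j in seq_along(x)) {
    swapped <- refs
    swapped[, j] <- x[j]
    direct <- mean(predict(toy$model@booster, xgboost::xgb.DMatrix(swapped),
                           outputmargin = TRUE) -
                   predict(toy$model@booster, xgboost::xgb.DMatrix(refs),
                           outputmargin = TRUE))
    expect_equal(unname(ex@attributions[j]), direct, tolerance = 1e-6)
  }
})

test_that("symmetric trees give symmetric attributions", {
  # hand-built leaf table: two identical stumps, one on f1, one on f2
  consStart <- c(0L, 1L, 2L, 3L, 4L)
  leafValue <- c(-1, 1, -1, 1)
  consFeat <- c(0L, 0L, 1L, 1L)
  consLo <- c(-Inf, 0, -Inf, 0)
  consHi <- c(0, Inf, 0, Inf)
  refs <- matrix(c(-1, -1), 1, 2)
  phi <- oomorph:::treeShapInterventionalCpp(consStart, leafValue, consFeat,
                                             consLo, consHi, c(1, 1), refs)
  expect_equal(phi[1], phi[2])
  expect_equal(sum(phi), 4)  # f(x) - f(ref) = (1+1) - (-1-1)
})

test_that("unused features receive exactly zero importance", {
  withr::with_seed(3, {
    X <- cbind(f1 = rnorm(300), f2 = 0, f3 = 0)  # only f1 is splittable
    y <- rbinom(300, 1, plogis(2 * X[, "f1"]))
  })
  bst <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                          eta = 0.3, max_depth = 2,
                                          nthread = 1, base_score = 0.5),
                            data = xgboost::xgb.DMatrix(X, label = y),
                            nrounds = 20, verbose = 0)
  model <- methods::new("ClassifierModel", booster = bst,
                        featureNames = colnames(X), params = list(),
                        bestIteration = NA_integer_, nTrainPos = 1L,
                        nTrainNeg = 1L)
  mr <- masvRanking(model, X, seed = 1)
  expect_equal(mr$feature[1], "f1")
  expect_gt(mr$masv[1], 0)
  expect_identical(mr$masv[2:3], c(0, 0))
  # ordering is stable under ties: tied zeros sorted by name
  expect_identical(mr$feature[2:3], c("f2", "f3"))
})

test_that("generator drivers surface at the top of the MASV ranking", {
  om <- outcomeModel(intercept = -46.5,
                     coefficients = c(oocyte_age = -0.30,
                                      ooplasm_roundness = 60))
  study <- generateCohortDataset(100, outcomeModel = om, seed = 11)
  fs <- assembleFeatureTable(study)
  sp <- patientSplit(sampleInfo(fs)$patient_id, seed = 1)
  model <- trainClassifier(fs, sp, seed = 1)
  te <- splitIdx(sp, "test")
  mr <- masvRanking(model, featureMatrix(fs)[te, ],
                    referenceSet = featureMatrix(fs)[splitIdx(sp, "train"), ],
                    maxReference = 100, seed = 1)
  expect_lte(which(mr$feature == "oocyte_age"), 3)
  expect_lte(which(mr$feature == "ooplasm_roundness"), 5)
  # the roundness signal is identifiable only up to its monotone
  # re-encodings (aspect ratio, circularity of the same region): the top
  # ranks must be exhausted by the age driver and that family
  roundnessFamily <- c("ooplasm_roundness", "ooplasm_aspect_ratio",
                       "ooplasm_circularity")
  expect_true(all(mr$feature[1:3] %in% c("oocyte_age", roundnessFamily)))
})

test_that("waterfall export preserves additivity and round-trips", {
  toy <- fitToyBooster(n = 300, p = 6)
  ex <- explainSample(toy$model, toy$X[5, ], toy$X[1:25, ], rowId = "O5")
  full <- exportWaterfall(ex, topK = 10)
  expect_equal(nrow(full$contributions), 6)  # no aggregation needed
  expect_equal(full$base_value + sum(full$contributions$attribution), full$fx)
  one <- exportWaterfall(ex, topK = 1)
  expect_equal(nrow(one$contributions), 2)
  expect_identical(one$contributions$feature[2], "other")
  expect_equal(one$base_value + sum(one$contributions$attribution), one$fx)
  expect_error(exportWaterfall(ex, topK = 0), "at least 1")
  f <- tempfile(fileext = ".json")
  writeWaterfall(full, f)
  back <- readWaterfall(f)
  expect_equal(back$base_value + sum(back$contributions$attribution),
               ex@fx, tolerance = 1e-9)
  expect_equal(back$probability, plogis(back$fx), tolerance = 1e-9)
  unlink(f)
})

test_that("schema mismatches and empty references are rejected", {
  toy <- fitToyBooster()
  expect_error(explainSample(toy$model, toy$X[1, 1:3], toy$X[1:5, ]),
               "schema mismatch")
  expect_error(explainSample(toy$model, toy$X[1, ],
                             toy$X[0, , drop = FALSE]), "non-empty")
})
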