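test_that("rocAuc equals the pairwise Mann-Whitney count", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.7, 0.3), c(1, 1, 0, 0)), 1)
  expect_equal(rocAuc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  withr::with_seed(3, {
    sc <- round(runif(200), 2)  # rounding forces ties
    y <- rbinom(200, 1, 0.4)
  })
  expect_equal(rocAuc(sc, y), aucBruteForce(sc, y), tolerance = 1e-12)
  # invariance under a strictly monotone transform
  expect_equal(rocAuc(qlogis(pmin(pmax(sc, 0.01), 0.99)), y), rocAuc(sc, y))
  expect_error(rocAuc(sc, rep(1, 200)), "both classes")
})

test_that("sensitivity and specificity follow the 2x2 table", {
  expect_equal(sensSpec(c(1, 1, 0, 0), c(1, 1, 0, 0)),
               c(sensitivity = 1, specificity = 1))
  expect_equal(sensSpec(rep(0, 4), c(1, 0, 1, 0)),
               c(sensitivity = 0, specificity = 1))
  # TP=3 FN=2 TN=6 FP=1
  pred <- c(rep(1, 3), rep(0, 2), rep(0, 6), 1)
  truth <- c(rep(1, 5), rep(0, 7))
  ss <- sensSpec(pred, truth)
  expect_equal(unname(ss["sensitivity"]), 0.6)
  expect_equal(unname(ss["specificity"]), 6 / 7, tolerance = 1e-12)
  # undefined rates are NA, not zero
  expect_true(is.na(sensSpec(c(0, 1), c(0, 0))["sensitivity"]))
  rep0 <- evalReport(c(0.2, 0.8, 0.6), c(0, 1, 0))
  expect_equal(sum(rep0@counts), rep0@n)
})

test_that("paired DeLong test is exact on identical scores and matches pROC", {
  withr::with_seed(11, {
    y <- rbinom(150, 1, 0.5)
    a <- rnorm(150) + y
    b <- 0.5 * a + rnorm(150)
  })
  same <- delongPaired(a, a, y)
  expect_equal(same@z, 0)
  expect_equal(same@p, 1)
  res <- delongPaired(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                        pROC::roc(y, b, quiet = TRUE), method = "delong",
                        paired = TRUE)
  expect_equal(res@z, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(res@p, ref$p.value, tolerance = 1e-9)
  expect_equal(delongVariance(a, y),
               pROC::var(pROC::roc(y, a, quiet = TRUE), method = "delong"),
               tolerance = 1e-9)
})

test_that("DeLong variance of a small fixture agrees with the bootstrap", {
  # fixture printed in full: 12 samples scored by two models
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  a <- c(0.9, 0.8, 0.7, 0.65, 0.4, 0.5, 0.3, 0.2, 0.6, 0.1, 0.45, 0.75)
  b <- c(0.7, 0.9, 0.6, 0.5, 0.55, 0.6, 0.2, 0.4, 0.3, 0.25, 0.5, 0.8)
  res <- delongPaired(a, b, y)
  boots <- withr::with_seed(99, vapply(seq_len(1e4), function(i) {
    idx <- sample(12, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    rocAuc(a[idx], y[idx]) - rocAuc(b[idx], y[idx])
  }, numeric(1)))
  expect_equal(res@varDiff, var(boots, na.rm = TRUE), tolerance = 0.15)
})

test_that("paired variance decomposes when the second score is pure noise", {
  withr::with_seed(4, {
    y <- rbinom(2000, 1, 0.5)
    a <- rnorm(2000) + 0.8 * y
    b <- rnorm(2000)
  })
  res <- delongPaired(a, b, y)
  vsum <- delongVariance(a, y) + delongVariance(b, y)
  expect_lt(abs(res@varDiff - vsum), 0.3 * vsum)
})

test_that("Welch's t matches closed-form and pooled-variance limits", {
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(welchT(c(1, 2, 3), c(1, 2, 3))$p, 1)
  res <- welchT(c(1, 2, 3), c(4, 5, 6))
  # closed form: t = (2 - 5) / sqrt(1/3 + 1/3) = -3.674
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  expect_equal(res$df, 4, tolerance = 1e-9)
  pooled <- t.test(c(1, 2, 3, 2.5), c(4, 5, 6, 5.5), var.equal = TRUE)
  welch <- welchT(c(1, 2, 3, 2.5), c(4, 5, 6, 5.5))
  expect_equal(welch$t, unname(pooled$statistic), tolerance = 1e-9)
  expect_error(welchT(c(1, 1), c(2, 2)), "zero variance")
  expect_error(welchT(1, c(1, 2)), "at least two")
})

test_that("PCA reduction counts components against generating factors", {
  withr::with_seed(6, {
    n <- 400
    f <- matrix(rnorm(n * 3), n, 3)
    load <- matrix(rnorm(3 * 12), 3, 12)
    X <- f %*% load + matrix(rnorm(n * 12, sd = 0.01), n, 12)
    colnames(X) <- paste0("v", 1:12)
  })
  red <- pcaReduce(X, 0.95)
  expect_equal(red$nComponents, 3)
  expect_equal(ncol(red$scores), 3)
  # threshold 1 recovers the full rank
  expect_equal(pcaReduce(X[, 1:5], 1.0)$nComponents, 5)
  # duplicated columns do not add components
  expect_equal(pcaReduce(cbind(X, X[, 1:4]), 0.95)$nComponents, 3)
  expect_warning(pcaReduce(cbind(X, const = 1), 0.95), "constant")
  # reconstruction error decreases monotonically with component count
  fit <- prcomp(scale(X))
  errs <- vapply(1:6, function(k) {
    rec <- fit$x[, 1:k, drop = FALSE] %*% t(fit$rotation[, 1:k, drop = FALSE])
    mean((scale(X) - rec)^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("ablation flags the driving group and spares a noise group", {
  fs <- makeToyFeatureSet(2500, beta = c(2.2, 1.2, rep(0, 4)), seed = 13,
                          groups = c("ooplasm", "relative", "zp", "zp",
                                     "relative", "relative"),
                          regions = c("ooplasm", "", "zp", "zp", "", ""))
  sp <- patientSplit(sampleInfo(fs)$patient_id, seed = 1)
  ab <- ablationEval(fs, sp, c("ooplasm", "zp"), seed = 1)
  oop <- ab[ab$group == "ooplasm", ]
  zp <- ab[ab$group == "zp", ]
  expect_lt(oop$auc, oop$aucFull)
  expect_lt(oop$p, 0.05)
  expect_gt(zp$p, 0.05)
  expect_error(ablationEval(fs, sp, character()), "no groups")
})

test_that("age bins and the age-exclusion filter follow the clinical strata", {
  ages <- c(25, 30, 34, 35, 38, 40, 44)
  expect_equal(as.character(ageBin(ages)),
               c("<30", "30-34", "30-34", "35-37", "38-39", ">=40", ">=40"))
  withr::with_seed(2, {
    sc <- runif(7); y <- c(0, 1, 0, 1, 0, 1, 1)
  })
  meta <- data.frame(oocyte_age = ages, clinic = "s",
                     patient_id = paste0("P", 1:7))
  res <- subgroupEval(sc, y, meta, by = "age", excludeAgeOver = 43,
                      method = "unpaired")
  expect_equal(res$n[res$subgroup == "overall"], 6)
  expect_equal(res$n[res$subgroup == "30-34"], 2)
  expect_equal(res$n[res$subgroup == ">=40"], 1)
  # single-class subgroups report NA AUC but keep counts
  expect_true(any(is.na(res$auc[res$subgroup != "overall"])))
})

test_that("subgroup analysis partitions samples and stays null-calibrated", {
  withr::with_seed(31, {
    n <- 600
    meta <- data.frame(
      oocyte_age = sample(24:44, n, replace = TRUE),
      clinic = sample(paste0("site_", LETTERS[1:4]), n, replace = TRUE),
      patient_id = sprintf("P%03d", rep(1:150, each = 4)))
    y <- rbinom(n, 1, 0.45)
    sc <- runif(n)  # performance uniform (chance) everywhere
  })
  res <- subgroupEval(sc, y, meta, by = "clinic", seed = 7, B = 300)
  expect_equal(sum(res$n[res$subgroup != "overall"]),
               res$n[res$subgroup == "overall"])
  # no subgroup should be flagged strongly on a uniform-performance null
  expect_true(all(res$p[res$subgroup != "overall"] > 0.01, na.rm = TRUE))
  resAge <- subgroupEval(sc, y, meta, by = "age", seed = 7, B = 300)
  expect_equal(sum(resAge$n[resAge$subgroup != "overall"]),
               resAge$n[resAge$subgroup == "overall"])
})
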