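test_that("AUC handles perfect separation, ties and the worked example", {
  expect_equal(rocAUC(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(rocAUC(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(rocAUC(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(rocAUC(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals the exhaustive pair-counting oracle", {
  for (i in 1:200) {
    n <- withr::with_seed(i, sample(4:30, 1))
    labels <- withr::with_seed(i * 7, {
      l <- rbinom(n, 1, 0.5)
      l[1] <- 0; l[2] <- 1  # guarantee both classes
      l
    })
    scores <- withr::with_seed(i * 13, round(runif(n), 2))  # force ties
    expect_equal(rocAUC(scores, labels), bruteAUC(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is monotone-invariant and complement-symmetric", {
  for (i in 1:25) {
    scores <- withr::with_seed(i, runif(20))
    labels <- withr::with_seed(i + 50, c(0, 1, rbinom(18, 1, 0.4)))
    a <- rocAUC(scores, labels)
    expect_equal(rocAUC(qlogis(scores), labels), a, tolerance = 1e-12)
    expect_equal(rocAUC(scores^3 + 2, labels), a, tolerance = 1e-12)
    expect_equal(a + rocAUC(scores, 1 - labels), 1, tolerance = 1e-12)
  }
})

test_that("confusion counts and Eq-style rates are exact", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  labels <- c(1, 0, 1, 1, 0, 0)
  cnt <- confusionAtThreshold(scores, labels, 0.5)
  expect_identical(cnt, c(TP = 2L, FP = 1L, TN = 2L, FN = 1L))
  expect_identical(confusionAtThreshold(scores, labels, 0)[["TN"]], 0L)
  expect_identical(confusionAtThreshold(scores, labels, 0)[["FN"]], 0L)
  expect_identical(confusionAtThreshold(scores, labels, 2)[["TP"]], 0L)
  expect_identical(confusionAtThreshold(scores, labels, 2)[["FP"]], 0L)

  expect_equal(sensSpec(c(TP = 9, FN = 1, TN = 8, FP = 2)),
               c(sensitivity = 90, specificity = 80))
  expect_equal(sensSpec(c(TP = 5, FN = 0, TN = 3, FP = 1))[["sensitivity"]],
               100)
  expect_warning(ss <- sensSpec(c(TP = 0, FN = 0, TN = 3, FP = 1)),
                 "undefined")
  expect_true(is.na(ss[["sensitivity"]]))
})

test_that("sensitivity/specificity match the formulas on random counts", {
  cnts <- withr::with_seed(77, matrix(rpois(4000, 8), ncol = 4))
  colnames(cnts) <- c("TP", "FP", "TN", "FN")
  cnts[cnts[, "TP"] + cnts[, "FN"] == 0, "TP"] <- 1
  cnts[cnts[, "TN"] + cnts[, "FP"] == 0, "TN"] <- 1
  for (i in seq_len(nrow(cnts))) {
    ss <- sensSpec(cnts[i, ])
    expect_identical(ss[["sensitivity"]], unname(
      100 * cnts[i, "TP"] / (cnts[i, "TP"] + cnts[i, "FN"])))
    expect_identical(ss[["specificity"]], unname(
      100 * cnts[i, "TN"] / (cnts[i, "TN"] + cnts[i, "FP"])))
  }
})

test_that("Youden thresholding matches exhaustive search, both orientations", {
  # perfectly separated: both rates 100%
  y <- youdenThreshold(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(y$sensitivity, 100)
  expect_equal(y$specificity, 100)
  expect_identical(y$orientation, ">=")

  # positives below the negatives: inverted orientation wins
  yi <- youdenThreshold(c(0.1, 0.7, 0.8, 0.9), c(1, 0, 0, 0))
  expect_identical(yi$orientation, "<=")
  expect_equal(yi$sensitivity, 100)
  expect_equal(yi$specificity, 100)
  expect_equal(yi$auc, 1)

  # 10-point toy vs brute force over a dense threshold sweep
  scores <- withr::with_seed(5, round(runif(10), 1))
  labels <- withr::with_seed(6, c(0, 1, rbinom(8, 1, 0.5)))
  y <- youdenThreshold(scores, labels)
  best <- -Inf
  for (t in seq(-0.05, 1.05, by = 0.01)) {
    for (orient in c(1, -1)) {
      pred <- if (orient == 1) scores >= t else scores <= t
      sens <- 100 * sum(pred & labels == 1) / sum(labels == 1)
      spec <- 100 * sum(!pred & labels == 0) / sum(labels == 0)
      best <- max(best, sens + spec)
    }
  }
  expect_equal(y$sensitivity + y$specificity, best, tolerance = 1e-9)
})

test_that("split plans partition cases as promised", {
  labs <- rep(c(0L, 1L), each = 10)
  loo <- makeSplits(1:20, labs, "loo")
  expect_length(loo@folds, 20)
  tests <- sort(unlist(lapply(loo@folds, `[[`, "test")))
  expect_identical(tests, 1:20)
  expect_true(all(vapply(loo@folds, function(f)
    length(f$test) == 1L, logical(1))))

  kf <- makeSplits(1:100, rep(c(0L, 1L), each = 50), "kfold", k = 10,
                   seed = 3)
  sizes <- vapply(kf@folds, function(f) length(f$test), integer(1))
  expect_identical(sizes, rep(10L, 10))
  expect_identical(sort(unlist(lapply(kf@folds, `[[`, "test"))), 1:100)
  # stratification: every test fold carries both classes evenly
  byFold <- vapply(kf@folds, function(f)
    sum(rep(c(0L, 1L), each = 50)[f$test]), integer(1))
  expect_true(all(byFold == 5L))

  pc <- makeSplits(1:200, rep(c(0L, 1L), each = 100), "percentage",
                   trainFraction = 0.5, seed = 9)
  f <- pc@folds[[1]]
  expect_length(f$train, 100)
  expect_length(f$test, 100)
  trLab <- rep(c(0L, 1L), each = 100)[f$train]
  expect_lte(abs(sum(trLab == 0) - sum(trLab == 1)), 1)

  expect_error(makeSplits(1:5, c(0, 0, 0, 1, 1), "kfold", k = 10),
               "at least")
  expect_error(makeSplits(1:4, c(0, 1, 0, 1), "loo"), NA)
  expect_error(makeSplits(1:6, c(1, 1, 1, 1, 1, 0), "loo"),
               "single class")
})

test_that("trial summaries reproduce reference mean/SD/CV rows exactly", {
  # reference per-trial AUC rows of the sampling-variability study
  lr5050 <- c(0.88, 0.92, 0.87, 0.96, 0.94)
  s <- summarizeTrials(lr5050)
  expect_equal(s$mean_2dp, 0.91)
  expect_equal(s$sd_2dp, 0.04)
  expect_identical(s$cv_percent, 4)

  nb5050 <- c(0.94, 0.96, 0.95, 0.96, 0.94)
  s <- summarizeTrials(nb5050)
  expect_equal(s$mean_2dp, 0.95)
  expect_equal(s$sd_2dp, 0.01)
  expect_identical(s$cv_percent, 1)

  expect_identical(summarizeTrials(c(0.9, 0.9, 0.9))$cv_percent, 0)
  one <- summarizeTrials(0.9)
  expect_true(is.na(one$sd) && is.na(one$cv_percent))
})

test_that("repeated trials are deterministic and rank a separable table", {
  df <- gaussianTable(30, 30, p = 3, sep = 2.5, seed = 91)
  m <- t(as.matrix(df[, 1:3]))
  rownames(m) <- c("echo_intensity", "heterogeneity", "kurtosis")
  ft <- seFromMatrix(m, df$label)

  ts <- runTrials(ft, modelKind = "naive_bayes", scheme = "loo",
                  baseSeed = 1)
  expect_gt(ts@meanAuc, 0.9)

  t1 <- runTrials(ft, modelKind = "logistic", scheme = "percentage",
                  trainFraction = 0.5, nTrials = 4, baseSeed = 11)
  t2 <- runTrials(ft, modelKind = "logistic", scheme = "percentage",
                  trainFraction = 0.5, nTrials = 4, baseSeed = 11)
  expect_identical(aucValues(t1), aucValues(t2))
  expect_length(aucValues(t1), 4)
  expect_false(is.na(t1@sdAuc))

  single <- runTrials(ft, modelKind = "naive_bayes", scheme = "kfold",
                      k = 5, nTrials = 1, baseSeed = 2)
  expect_true(is.na(single@sdAuc))
  expect_true(is.na(single@cvPercent))
})

test_that("per-feature performance reports oriented operating points", {
  ft <- tinyCohort()$ft
  fp <- featurePerformance(ft)
  expect_identical(fp$feature, textureFeatureNames())
  expect_true(all(fp$orientation %in% c(">=", "<=")))
  expect_true(all(fp$sensitivity >= 0 & fp$sensitivity <= 100))
  expect_true(all(fp$specificity >= 0 & fp$specificity <= 100))
  expect_true(all(fp$auc >= 0.5 - 1e-9))
})
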