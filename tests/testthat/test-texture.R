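test_that("min-max quantization follows the floor formula", {
  # hand evaluation: level = floor((x - min) * L / (max - min + 1))
  toy <- matrix(c(0, 8, 16, 24, 32, 40, 48, 56, 255), 3, byrow = TRUE)
  q <- quantizeROI(toy, levels = 8)
  expect_identical(q@grid,
                   matrix(as.integer(floor(toy * 8 / 256)), 3))

  expect_true(all(quantizeROI(matrix(7, 16, 16), levels = 32)@grid == 0L))

  full <- quantizeROI(matrix(0:255, 16), levels = 32)
  expect_identical(sort(unique(as.vector(full@grid))), 0:31)
  # monotone: higher gray level never maps to a lower quantized level
  expect_true(all(diff(full@grid[order(0:255)]) >= 0))

  expect_error(quantizeROI(matrix(1, 4, 4), levels = 1), "levels")
  expect_error(quantizeROI(matrix(1, 10, 10), roi = c(2, 2, 2, 6)), "ROI")
})

test_that("first-order features match closed-form moment values", {
  expect_equal(firstOrderFeatures(matrix(9.5, 8, 8)),
               c(echo_intensity = 9.5, heterogeneity = 0, skewness = 0,
                 kurtosis = 0))

  # {0,0,0,255}: a 3:1 two-point distribution with closed-form moments
  f <- firstOrderFeatures(matrix(c(0, 0, 0, 255), 2))
  expect_equal(f[["echo_intensity"]], 63.75)
  expect_equal(f[["heterogeneity"]], 127.5)
  expect_equal(f[["skewness"]], 2 / sqrt(3), tolerance = 1e-12)
  p <- 1 / 4  # Bernoulli excess kurtosis (1 - 6pq) / (pq)
  expect_equal(f[["kurtosis"]], (1 - 6 * p * (1 - p)) / (p * (1 - p)),
               tolerance = 1e-12)

  g <- withr::with_seed(11, matrix(rnorm(4096, 100, 10), 64))
  expect_lt(abs(firstOrderFeatures(g)[["kurtosis"]]), 0.2)
})

test_that("GLCM of the 2x2 toy and its Haralick features are exact", {
  q <- quantizeROI(matrix(c(0, 0, 0, 1), 2, byrow = TRUE), levels = 2)
  g <- computeGLCM(q, distance = 1, directions = 0, symmetric = TRUE)
  expect_equal(glcmProbabilities(g),
               matrix(c(0.5, 0.25, 0.25, 0), 2, byrow = TRUE))
  f <- glcmFeatures(g)
  expect_equal(f[["asm"]], 0.375, tolerance = 1e-9)
  expect_equal(f[["contrast"]], 0.5, tolerance = 1e-9)
  expect_equal(f[["dissimilarity"]], 0.5, tolerance = 1e-9)
  expect_equal(f[["entropy"]], -(0.5 * log(0.5) + 0.5 * log(0.25)),
               tolerance = 1e-9)
  expect_equal(f[["entropy"]], 1.0397, tolerance = 1e-4)
})

test_that("degenerate GLCMs behave as the formulas dictate", {
  q <- quantizeROI(matrix(5, 8, 8), levels = 4)
  g <- computeGLCM(q)
  expect_equal(glcmProbabilities(g)[1, 1], 1)
  f <- glcmFeatures(g)
  expect_equal(f[["asm"]], 1)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_equal(f[["glcm_correlation"]], 0)  # zero marginal SD convention

  # a single row cannot form vertical pairs at distance 2
  thin <- new("QuantizedROI", levels = 2L,
              grid = matrix(0:1, 1, 8), nPixels = 8L)
  expect_error(computeGLCM(thin, distance = 2, directions = 90), "no pairs")
})

test_that("GLCM equals brute-force pair enumeration on random regions", {
  for (i in 1:40) {
    h <- sample(2:24, 1); w <- sample(2:24, 1); ng <- sample(2:8, 1)
    q <- randomQROI(h, w, ng, seed = 1000 + i)
    for (sym in c(TRUE, FALSE)) {
      g <- computeGLCM(q, 1, c(0, 45, 90, 135), symmetric = sym)
      expect_equal(glcmProbabilities(g),
                   bruteGLCM(q@grid, ng, 1, symmetric = sym),
                   tolerance = 1e-12)
    }
    # symmetric marginals coincide, correlation stays in [-1, 1]
    gs <- computeGLCM(q, 1, c(0, 45, 90, 135), symmetric = TRUE)
    P <- glcmProbabilities(gs)
    expect_equal(rowSums(P), colSums(P), tolerance = 1e-12)
    expect_lte(abs(glcmFeatures(gs)[["glcm_correlation"]]), 1 + 1e-12)
    expect_equal(sum(P), 1, tolerance = 1e-9)
  }
})

test_that("run-length decomposition of the printed row is exact", {
  q <- quantizeROI(matrix(c(0, 0, 1, 1, 1, 2), 1), levels = 3)
  r <- computeRLM(q, directions = 0)
  expect_identical(r@nRuns, 3L)
  cnt <- rlmCounts(r)
  expect_equal(cnt[1, 2], 1)  # level 0, length 2
  expect_equal(cnt[2, 3], 1)  # level 1, length 3
  expect_equal(cnt[3, 1], 1)  # level 2, length 1
  expect_equal(sum(cnt), 3)
  f <- rlmFeatures(r)
  expect_equal(f[["short_run"]], (1 / 4 + 1 / 9 + 1) / 3, tolerance = 1e-9)
  expect_equal(f[["short_run"]], 0.4537, tolerance = 1e-4)
  expect_equal(f[["long_run"]], 14 / 3, tolerance = 1e-9)
  expect_equal(f[["gl_nonuniformity"]], 1 / 3, tolerance = 1e-9)
  expect_equal(f[["rl_nonuniformity"]], 1 / 3, tolerance = 1e-9)
  expect_equal(f[["run_percentage"]], 0.5, tolerance = 1e-9)
})

test_that("run-length closed forms hold for constant and checkerboard", {
  n <- 12
  q <- quantizeROI(matrix(3, 1, n), levels = 4)
  f <- rlmFeatures(computeRLM(q, directions = 0))
  expect_equal(f[["short_run"]], 1 / n^2)
  expect_equal(f[["long_run"]], n^2)
  expect_equal(f[["gl_nonuniformity"]], 1)
  expect_equal(f[["rl_nonuniformity"]], 1)
  expect_equal(f[["run_percentage"]], 1 / n)

  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  qcb <- new("QuantizedROI", levels = 2L,
             grid = matrix(as.integer(cb), 8), nPixels = 64L)
  fcb <- rlmFeatures(computeRLM(qcb, directions = 0))
  expect_equal(fcb[["short_run"]], 1)
  expect_equal(fcb[["long_run"]], 1)
  expect_equal(fcb[["run_percentage"]], 1)
})

test_that("RLM equals a brute-force scan-line oracle on random regions", {
  for (i in 1:40) {
    h <- sample(2:24, 1); w <- sample(2:24, 1); ng <- sample(2:8, 1)
    q <- randomQROI(h, w, ng, seed = 2000 + i)
    r <- computeRLM(q)
    expect_equal(unname(rlmCounts(r)), unname(bruteRLM(q@grid, ng)),
                 tolerance = 0)
    # Cauchy-Schwarz on the run-length distribution
    f <- rlmFeatures(r)
    expect_gte(f[["short_run"]] * f[["long_run"]], 1 - 1e-12)
    expect_gt(f[["run_percentage"]], 0)
    expect_lte(f[["run_percentage"]], 1)
  }
})

test_that("feature table aggregates ROI vectors by unweighted mean", {
  img <- simulateSpeckleField(160, 160, 2, 40, 15, seed = 21)
  roi <- data.frame(x0 = 8L, y0 = 8L, x1 = 72L, y1 = 72L)
  one <- list(list(image = img, rois = ROISet("a", roi)))
  ft1 <- extractFeatureTable(one)
  direct <- liverQUS:::.roiFeatures(img, c(8, 8, 72, 72), 32, 1,
                                    c(0, 45, 90, 135), TRUE)
  expect_equal(unname(SummarizedExperiment::assay(ft1)[, 1]),
               unname(direct))

  # two identical ROIs average to the same vector
  two <- list(list(image = img, rois = ROISet("a", rbind(roi, roi))))
  ft2 <- extractFeatureTable(two)
  expect_equal(SummarizedExperiment::assay(ft2)[, 1],
               SummarizedExperiment::assay(ft1)[, 1])
})

test_that("extracted tables are complete and finite on a synthetic cohort", {
  ft <- tinyCohort()$ft
  m <- SummarizedExperiment::assay(ft)
  expect_identical(rownames(m), textureFeatureNames())
  expect_identical(ncol(m), 8L)
  expect_true(all(is.finite(m)))
  expect_true(all(m["run_percentage", ] > 0 & m["run_percentage", ] <= 1))
  expect_true(all(m["asm", ] > 0 & m["asm", ] <= 1))
  cd <- SummarizedExperiment::colData(ft)
  expect_identical(as.vector(table(cd$label)), c(4L, 4L))
})

test_that("features are stable under ROI translation in stationary texture", {
  # paired differences across translated ROIs stay well under the
  # between-seed spread of the features themselves
  diffs <- NULL
  vals <- NULL
  for (s in 1:50) {
    img <- simulateSpeckleField(192, 192, 2, 45, 16, seed = 300 + s)
    a <- liverQUS:::.roiFeatures(img, c(8, 8, 72, 72), 32, 1,
                                 c(0, 45, 90, 135), TRUE)
    b <- liverQUS:::.roiFeatures(img, c(100, 100, 164, 164), 32, 1,
                                 c(0, 45, 90, 135), TRUE)
    diffs <- rbind(diffs, a - b)
    vals <- rbind(vals, a, b)
  }
  pooledSd <- apply(vals, 2, sd)
  meanAbsDiff <- abs(colMeans(diffs))
  expect_true(all(meanAbsDiff < 0.5 * pooledSd + 1e-9))
})
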