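test_that("logistic regression matches the maximum-likelihood oracle", {
  df <- gaussianTable(100, 100, p = 2, sep = 1.2, seed = 31)
  fit <- fitLogistic(df)
  ours <- coef(fit)
  ref <- glm(label ~ f1 + f2, binomial(), data = df)
  expect_equal(unname(ours), unname(stats::coef(ref)), tolerance = 1e-4)
  expect_true(fit@converged)
  expect_false(fit@separation)

  # predictions agree too
  p <- predictProba(fit, df[, c("f1", "f2")])
  expect_equal(unname(p), unname(fitted(ref)), tolerance = 1e-6)
})

test_that("logistic symmetry, separation and degenerate inputs", {
  # balanced data symmetric about zero: intercept vanishes
  x <- c(-3, -2, -1, 1, 2, 3)
  df <- data.frame(f1 = x, label = as.integer(x > 0))
  # perfectly separated: flagged, not an error
  fit <- fitLogistic(df)
  expect_true(fit@separation)

  dfs <- data.frame(f1 = rep(c(-2, -1, 1, 2), 10),
                    label = rep(c(0L, 1L, 0L, 1L), 10))
  fs <- fitLogistic(dfs)
  expect_lt(abs(coef(fs)[["intercept"]]), 1e-6)

  expect_error(fitLogistic(data.frame(f1 = rnorm(5), label = rep(1L, 5))),
               "both classes")
  expect_error(fitLogistic(data.frame(f1 = rep(2, 10),
                                      label = rep(c(0L, 1L), 5))),
               "constant")
})

test_that("naive Bayes posterior equals the closed-form Bayes rule", {
  # symmetric likelihoods: posterior is exactly 1/2 at the midpoint
  df <- data.frame(f1 = c(-2, 0, 2, 4), label = c(0L, 0L, 1L, 1L))
  fit <- fitNaiveBayes(df)
  expect_equal(predictProba(fit, c(f1 = 1)), 0.5, tolerance = 1e-12)

  # hand-computed posterior on a 4-point training set
  post <- function(x, m0, v0, m1, v1, p1 = 0.5) {
    l0 <- dnorm(x, m0, sqrt(v0)) * (1 - p1)
    l1 <- dnorm(x, m1, sqrt(v1)) * p1
    l1 / (l0 + l1)
  }
  # model works on standardized scale; reproduce it explicitly
  mu <- mean(df$f1); sc <- sd(df$f1)
  z <- (df$f1 - mu) / sc
  for (x in c(-1, 0.3, 1.7, 5)) {
    zx <- (x - mu) / sc
    expected <- post(zx, mean(z[1:2]), var(z[1:2]), mean(z[3:4]),
                     var(z[3:4]))
    expect_equal(predictProba(fit, c(f1 = x)), expected,
                 tolerance = 1e-10)
  }

  # duplicated feature double-counts evidence under independence
  df2 <- data.frame(f1 = df$f1, f2 = df$f1, label = df$label)
  fit2 <- fitNaiveBayes(df2)
  p1 <- predictProba(fit, c(f1 = 1.7))
  p2 <- predictProba(fit2, c(f1 = 1.7, f2 = 1.7))
  expect_gt(abs(p2 - 0.5), abs(p1 - 0.5))

  expect_error(fitNaiveBayes(data.frame(f1 = rnorm(3),
                                        label = c(0L, 1L, 1L))),
               "at least 2")
})

test_that("MLP is seed-deterministic, separates linear data, solves XOR", {
  df <- gaussianTable(20, 20, p = 2, sep = 3, seed = 41)
  a <- fitMLP(df, seed = 5)
  b <- fitMLP(df, seed = 5)
  expect_identical(a@W1, b@W1)
  expect_identical(a@W2, b@W2)
  c2 <- fitMLP(df, seed = 6)
  expect_false(identical(a@W1, c2@W1))

  acc <- mean((predictProba(a, df[, 1:2]) >= 0.5) == (df$label == 1))
  expect_identical(acc, 1)

  xor <- data.frame(f1 = rep(c(0, 0, 1, 1), 25),
                    f2 = rep(c(0, 1, 0, 1), 25),
                    label = rep(c(0L, 1L, 1L, 0L), 25))
  fx <- fitMLP(xor, seed = 2)
  accx <- mean((predictProba(fx, xor[, 1:2]) >= 0.5) == (xor$label == 1))
  expect_gt(accx, 0.9)

  expect_error(fitMLP(df), "seed")
})

test_that("probability predictions respect the model structure", {
  # zero-weight logistic scores exactly 1/2
  m <- new("LogisticModel", kind = "logistic", featureNames = "f1",
           center = c(f1 = 0), scale = c(f1 = 1),
           coefficients = c(0, 0), converged = TRUE, iterations = 1L,
           separation = FALSE)
  expect_equal(predictProba(m, c(f1 = 3)), 0.5)

  # a positive coefficient makes the output strictly increasing
  df <- gaussianTable(50, 50, p = 2, sep = 1.5, seed = 51)
  fit <- fitLogistic(df)
  stopifnot(coef(fit)[["f1"]] > 0)
  xs <- seq(-2, 2, length.out = 9)
  ps <- vapply(xs, function(x)
    predictProba(fit, c(f1 = x, f2 = 0)), numeric(1))
  expect_true(all(diff(ps) > 0))

  expect_error(predictProba(fit, c(f1 = 1)), "missing feature.*f2")

  nb <- fitNaiveBayes(df)
  probs <- predictProba(nb, df[, 1:2])
  expect_true(all(probs >= 0 & probs <= 1))
})

test_that("all three models beat chance on a separated synthetic problem", {
  for (s in 1:10) {
    df <- gaussianTable(100, 100, p = 2, sep = 2, seed = 600 + s)
    for (kind in c("logistic", "naive_bayes", "mlp")) {
      fit <- liverQUS:::.fitModel(kind, df, c("f1", "f2"), seed = s)
      auc <- rocAUC(predictProba(fit, df[, 1:2]), df$label)
      expect_gt(auc, 0.8)
    }
  }
})

test_that("repeated seed-free fits are bit-identical", {
  df <- gaussianTable(60, 60, p = 3, sep = 1, seed = 71)
  expect_identical(fitLogistic(df)@coefficients,
                   fitLogistic(df)@coefficients)
  expect_identical(fitNaiveBayes(df)@means, fitNaiveBayes(df)@means)
})

test_that("JSON serialization round-trips predictions exactly", {
  df <- gaussianTable(40, 40, p = 3, sep = 1.5, seed = 81)
  grid <- as.matrix(gaussianTable(10, 10, p = 3, sep = 1.5,
                                  seed = 82)[, 1:3])
  for (kind in c("logistic", "naive_bayes", "mlp")) {
    fit <- liverQUS:::.fitModel(kind, df, c("f1", "f2", "f3"), seed = 3)
    path <- tempfile(fileext = ".json")
    writeModel(fit, path)
    back <- readModel(path)
    expect_identical(predictProba(back, grid), predictProba(fit, grid))
    unlink(path)
  }
  tmp <- tempfile()
  jsonlite::write_json(list(format = "x"), tmp, auto_unbox = TRUE)
  expect_error(readModel(tmp), "not a liverQUS model")
  unlink(tmp)
})
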