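## The three diagnostic models: logistic regression (ridge-stabilized
## Newton maximum likelihood), Gaussian naive Bayes, and a
## single-hidden-layer perceptron trained by full-batch backpropagation.
## All models standardize features with training-fold statistics and
## output the probability of advanced fibrosis (class 1).

## Pull a numeric design matrix + 0/1 labels out of a feature table
## SummarizedExperiment or a plain data.frame with a `label` column.
.designMatrix <- function(x, features = NULL, requireLabels = TRUE) {
  if (is(x, "SummarizedExperiment")) {
    m <- t(SummarizedExperiment::assay(x, "features"))
    y <- SummarizedExperiment::colData(x)$label
  } else {
    df <- as.data.frame(x)
    y <- if ("label" %in% names(df)) df$label else NULL
    num <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "label")
    m <- as.matrix(df[, num, drop = FALSE])
  }
  if (is.null(features)) features <- colnames(m)
  miss <- setdiff(features, colnames(m))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  m <- m[, features, drop = FALSE]
  if (requireLabels) {
    if (is.null(y) || anyNA(y)) stop("labeled data required")
    y <- as.integer(y)
    if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
    if (length(unique(y)) < 2L)
      stop("both classes must be present in the training data")
  }
  list(X = m, y = y)
}

.standardizeFit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl,
       Z = sweep(sweep(X, 2, ctr), 2, scl, "/"))
}

.standardizeApply <- function(model, X) {
  sweep(sweep(X, 2, model@center), 2, model@scale, "/")
}

#' Fit a binary logistic regression by penalized maximum likelihood
#'
#' Newton-Raphson iterations on the ridge-stabilized log-likelihood
#' (ridge 1e-8 on the standardized coefficients), stopping when the
#' log-likelihood changes by less than 1e-8 or after 100 iterations.
#' Features are standardized internally with the training data;
#' \code{coef()} returns coefficients transformed back to the original
#' feature scale. Quasi-complete separation (diverging coefficient norm)
#' returns the ridge solution with the \code{separation} flag set rather
#' than failing.
#'
#' @param x feature-table SummarizedExperiment or data.frame with a
#'   \code{label} column.
#' @param features ordered predictor subset (default: all features).
#' @return A \linkS4class{LogisticModel}.
#' @export
fitLogistic <- function(x, features = NULL) {
  d <- .designMatrix(x, features)
  if (all(apply(d$X, 2, stats::sd) == 0))
    stop("design contains only constant features")
  st <- .standardizeFit(d$X)
  Z <- cbind(1, st$Z)
  y <- d$y
  p1 <- ncol(Z)
  ridge <- 1e-8
  beta <- numeric(p1)
  penLik <- function(b) {
    eta <- drop(Z %*% b)
    sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta)))) -
      ridge * sum(b^2) / 2
  }
  llOld <- penLik(beta); converged <- FALSE; iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(Z %*% beta)
    mu <- stats::plogis(eta)
    W <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(Z, Z * W) + diag(ridge, p1)
    gr <- crossprod(Z, y - mu) - ridge * beta
    step <- drop(solve(H, gr))
    ## step-halving: never let the penalized log-likelihood decrease
    ll <- penLik(beta + step)
    halvings <- 0L
    while ((!is.finite(ll) || ll < llOld) && halvings < 30L) {
      step <- step / 2
      ll <- penLik(beta + step)
      halvings <- halvings + 1L
    }
    beta <- beta + step
    if (is.finite(ll) && abs(ll - llOld) < 1e-8) { converged <- TRUE; break }
    llOld <- ll
    if (iter >= 100L) break
  }
  mu <- stats::plogis(drop(Z %*% beta))
  separation <- max(abs(beta[-1])) > 10 && all(abs(y - mu) < 1e-3)
  if (!converged && max(abs(beta[-1])) > 50) separation <- TRUE
  if (!converged && !separation) {
    cond <- simpleError(sprintf(
      "logistic regression did not converge in %d iterations", iter))
    cond$lastIterate <- beta
    stop(cond)
  }
  new("LogisticModel", kind = "logistic",
      featureNames = colnames(d$X), center = st$center, scale = st$scale,
      coefficients = beta, converged = converged, iterations = iter,
      separation = separation)
}

#' @describeIn fitLogistic coefficients on the original feature scale
#'   (intercept first).
#' @param object a \linkS4class{LogisticModel}.
#' @param ... ignored.
#' @export
setMethod("coef", "LogisticModel", function(object, ...) {
  b <- object@coefficients
  raw <- b[-1] / object@scale
  c(intercept = b[1] - sum(b[-1] * object@center / object@scale),
    stats::setNames(raw, object@featureNames))
})

#' Fit a Gaussian naive Bayes classifier
#'
#' Per class and feature, a univariate Gaussian class-conditional is
#' estimated (sample mean and variance) together with empirical class
#' priors. Variances are floored at 1e-9 times the pooled variance of
#' the feature to keep the posterior finite for degenerate features.
#' Posteriors are evaluated in log space.
#'
#' @inheritParams fitLogistic
#' @return A \linkS4class{NaiveBayesModel}.
#' @export
fitNaiveBayes <- function(x, features = NULL) {
  d <- .designMatrix(x, features)
  if (sum(d$y == 0) < 2 || sum(d$y == 1) < 2)
    stop("need at least 2 images per class")
  st <- .standardizeFit(d$X)
  Z <- st$Z
  pooled <- apply(Z, 2, stats::var)
  floorv <- pmax(1e-9 * pooled, 1e-12)
  mns <- rbind(colMeans(Z[d$y == 0, , drop = FALSE]),
               colMeans(Z[d$y == 1, , drop = FALSE]))
  vrs <- rbind(apply(Z[d$y == 0, , drop = FALSE], 2, stats::var),
               apply(Z[d$y == 1, , drop = FALSE], 2, stats::var))
  vrs <- pmax(vrs, rep(floorv, each = 2))
  new("NaiveBayesModel", kind = "naive_bayes",
      featureNames = colnames(d$X), center = st$center, scale = st$scale,
      priors = c(mean(d$y == 0), mean(d$y == 1)), means = mns,
      variances = vrs)
}

#' Fit a single-hidden-layer perceptron
#'
#' One hidden layer of \code{ceiling((p + 2) / 2)} sigmoid units and a
#' sigmoid output, trained by full-batch backpropagation of the
#' squared-error loss (per-example gradients accumulated over the whole
#' training set) with learning rate 0.3 and momentum 0.2 for 500 epochs
#' on standardized inputs -- the conventional default geometry (mean of
#' attribute and class counts) and learning schedule for this
#' architecture. Training is deterministic given the seed, which only
#' controls weight initialization (uniform on [-0.5, 0.5]).
#'
#' @inheritParams fitLogistic
#' @param seed RNG seed for weight initialization (required).
#' @param hidden hidden units; default \code{ceiling((p + 2) / 2)}.
#' @param learningRate,momentum,epochs training schedule.
#' @return An \linkS4class{MLPModel}.
#' @export
fitMLP <- function(x, features = NULL, seed, hidden = NULL,
                   learningRate = 0.3, momentum = 0.2, epochs = 500) {
  if (missing(seed)) stop("fitMLP requires an explicit seed")
  d <- .designMatrix(x, features)
  st <- .standardizeFit(d$X)
  Z <- st$Z
  y <- d$y
  p <- ncol(Z); n <- nrow(Z)
  if (is.null(hidden)) hidden <- ceiling((p + 2) / 2)
  w <- withr::with_seed(as.integer(seed),
                        stats::runif(hidden * p + hidden + hidden + 1,
                                     -0.5, 0.5))
  W1 <- matrix(w[seq_len(hidden * p)], hidden, p)
  b1 <- w[hidden * p + seq_len(hidden)]
  W2 <- w[hidden * p + hidden + seq_len(hidden)]
  b2 <- w[length(w)]
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  for (ep in seq_len(epochs)) {
    A <- stats::plogis(Z %*% t(W1) + matrix(b1, n, hidden, byrow = TRUE))
    o <- drop(stats::plogis(A %*% W2 + b2))
    if (!all(is.finite(o)))
      stop(sprintf("non-finite MLP activations at epoch %d", ep))
    dOut <- (o - y) * o * (1 - o)            # dSE/dz, summed over examples
    dA <- (dOut %o% W2) * A * (1 - A)
    gW2 <- drop(crossprod(A, dOut)); gb2 <- sum(dOut)
    gW1 <- crossprod(dA, Z); gb1 <- colSums(dA)
    vW2 <- momentum * vW2 - learningRate * gW2
    vb2 <- momentum * vb2 - learningRate * gb2
    vW1 <- momentum * vW1 - learningRate * gW1
    vb1 <- momentum * vb1 - learningRate * gb1
    W2 <- W2 + vW2; b2 <- b2 + vb2; W1 <- W1 + vW1; b1 <- b1 + vb1
  }
  new("MLPModel", kind = "mlp", featureNames = colnames(d$X),
      center = st$center, scale = st$scale, W1 = W1, b1 = b1, W2 = W2,
      b2 = b2, seed = as.integer(seed))
}

## ----- prediction ----------------------------------------------------------

.predictInput <- function(model, newdata) {
  if (is(newdata, "SummarizedExperiment")) {
    m <- t(SummarizedExperiment::assay(newdata, "features"))
  } else if (is.numeric(newdata) && is.null(dim(newdata))) {
    m <- matrix(newdata, 1, dimnames = list(NULL, names(newdata)))
  } else {
    m <- as.matrix(as.data.frame(newdata)[, , drop = FALSE])
  }
  miss <- setdiff(model@featureNames, colnames(m))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  .standardizeApply(model, m[, model@featureNames, drop = FALSE])
}

#' @rdname predictProba
setMethod("predictProba", "LogisticModel", function(model, newdata) {
  Z <- .predictInput(model, newdata)
  drop(stats::plogis(cbind(1, Z) %*% model@coefficients))
})

#' @rdname predictProba
setMethod("predictProba", "NaiveBayesModel", function(model, newdata) {
  Z <- .predictInput(model, newdata)
  logLik <- function(cls) {
    mu <- model@means[cls, ]; v <- model@variances[cls, ]
    rowSums(-0.5 * log(2 * pi * matrix(v, nrow(Z), ncol(Z), byrow = TRUE)) -
            sweep(Z, 2, mu)^2 / (2 * matrix(v, nrow(Z), ncol(Z),
                                            byrow = TRUE))) +
      log(model@priors[cls])
  }
  l0 <- logLik(1); l1 <- logLik(2)
  drop(1 / (1 + exp(l0 - l1)))
})

#' @rdname predictProba
setMethod("predictProba", "MLPModel", function(model, newdata) {
  Z <- .predictInput(model, newdata)
  A <- stats::plogis(Z %*% t(model@W1) +
                     matrix(model@b1, nrow(Z), length(model@b1),
                            byrow = TRUE))
  drop(stats::plogis(A %*% model@W2 + model@b2))
})

## ----- serialization -------------------------------------------------------

#' Serialize / load a trained model as JSON
#'
#' Writes a versioned JSON document (kind, feature names, standardization
#' constants, kind-specific parameters) at full double precision, so a
#' round-trip through \code{readModel} reproduces predictions exactly.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param path JSON file path.
#' @return \code{writeModel}: the path, invisibly; \code{readModel}: the
#'   reconstructed model.
#' @export
writeModel <- function(model, path) {
  base <- list(format = "liverQUS-model", version = 1L,
               kind = model@kind, featureNames = model@featureNames,
               center = model@center, scale = model@scale)
  pars <- switch(model@kind,
    logistic = list(coefficients = model@coefficients,
                    converged = model@converged,
                    iterations = model@iterations,
                    separation = model@separation),
    naive_bayes = list(priors = model@priors,
                       means = model@means, variances = model@variances),
    mlp = list(W1 = model@W1, b1 = model@b1, W2 = model@W2, b2 = model@b2,
               seed = model@seed))
  jsonlite::write_json(c(base, pars), path, digits = I(17),
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "liverQUS-model"))
    stop("not a liverQUS model file")
  ctr <- stats::setNames(as.numeric(j$center), j$featureNames)
  scl <- stats::setNames(as.numeric(j$scale), j$featureNames)
  switch(j$kind,
    logistic = new("LogisticModel", kind = "logistic",
                   featureNames = j$featureNames, center = ctr, scale = scl,
                   coefficients = as.numeric(j$coefficients),
                   converged = j$converged,
                   iterations = as.integer(j$iterations),
                   separation = j$separation),
    naive_bayes = new("NaiveBayesModel", kind = "naive_bayes",
                      featureNames = j$featureNames, center = ctr,
                      scale = scl, priors = as.numeric(j$priors),
                      means = as.matrix(j$means),
                      variances = as.matrix(j$variances)),
    mlp = new("MLPModel", kind = "mlp", featureNames = j$featureNames,
              center = ctr, scale = scl, W1 = as.matrix(j$W1),
              b1 = as.numeric(j$b1), W2 = as.numeric(j$W2),
              b2 = as.numeric(j$b2), seed = as.integer(j$seed)),
    stop("unknown model kind: ", j$kind))
}

## dispatch on kind string, shared by evaluation and pipeline code
.fitModel <- function(kind, x, features, seed = NULL) {
  switch(kind,
    logistic = fitLogistic(x, features),
    naive_bayes = fitNaiveBayes(x, features),
    mlp = fitMLP(x, features, seed = if (is.null(seed)) 1L else seed),
    stop("unknown classifier kind: ", kind))
}
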