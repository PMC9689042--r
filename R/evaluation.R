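## ROC/AUC, sensitivity/specificity, threshold selection, train-test
## sampling schemes and trial-to-trial AUC variability summaries.

.checkScores <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present among the labels")
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs
#' in which the positive scores higher, ties counted as one half.
#' Computed from mid-ranks, so it is exact under ties and invariant to
#' strictly monotone transforms of the scores.
#'
#' @param scores numeric scores (e.g. predicted probabilities).
#' @param labels 0/1 labels (1 = advanced fibrosis).
#' @return AUC in [0, 1].
#' @export
#' @examples
#' rocAUC(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
rocAUC <- function(scores, labels) {
  labels <- .checkScores(scores, labels)
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Confusion counts at a score threshold
#'
#' Predicted positive means score >= threshold.
#'
#' @inheritParams rocAUC
#' @param threshold decision threshold.
#' @return Named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
confusionAtThreshold <- function(scores, labels, threshold) {
  labels <- .checkScores(scores, labels)
  pred <- scores >= threshold
  c(TP = sum(pred & labels == 1L), FP = sum(pred & labels == 0L),
    TN = sum(!pred & labels == 0L), FN = sum(!pred & labels == 1L))
}

#' Sensitivity and specificity from confusion counts
#'
#' Sensitivity = 100 TP / (TP + FN); specificity = 100 TN / (TN + FP),
#' both in percent. A zero denominator yields NA with a warning rather
#' than a silent zero.
#'
#' @param counts named vector with elements TP, FP, TN, FN.
#' @return Named numeric vector \code{c(sensitivity, specificity)} in
#'   percent.
#' @export
sensSpec <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% names(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  sens <- if (counts["TP"] + counts["FN"] > 0)
    100 * counts[["TP"]] / (counts[["TP"]] + counts[["FN"]]) else {
      warning("sensitivity undefined: TP + FN = 0"); NA_real_
    }
  spec <- if (counts["TN"] + counts["FP"] > 0)
    100 * counts[["TN"]] / (counts[["TN"]] + counts[["FP"]]) else {
      warning("specificity undefined: TN + FP = 0"); NA_real_
    }
  c(sensitivity = sens, specificity = spec)
}

#' Youden-optimal operating point of one score
#'
#' Sweeps all midpoints between consecutive distinct observed scores
#' (plus sentinels below and above the range) and both orientations
#' (positive means score >= t, or score <= t for features that decrease
#' with disease), and returns the point maximizing sensitivity +
#' specificity; ties break toward higher specificity, then toward the
#' ">=" orientation.
#'
#' @inheritParams rocAUC
#' @return A list: \code{threshold}, \code{orientation} (">=" or "<="),
#'   \code{sensitivity}, \code{specificity} (percent), \code{auc} (of
#'   the oriented score), and \code{counts}.
#' @export
youdenThreshold <- function(scores, labels) {
  labels <- .checkScores(scores, labels)
  s <- sort(unique(scores))
  cand <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            s[length(s)] + 1)
  best <- NULL
  for (orient in c(">=", "<=")) {
    sc <- if (orient == ">=") scores else -scores
    for (t in cand) {
      tt <- if (orient == ">=") t else -t
      cnt <- confusionAtThreshold(sc, labels, tt)
      ss <- sensSpec(cnt)
      cur <- list(threshold = t, orientation = orient,
                  sensitivity = ss[["sensitivity"]],
                  specificity = ss[["specificity"]],
                  youden = sum(ss) - 100, counts = cnt)
      if (is.null(best) || cur$youden > best$youden + 1e-12 ||
          (abs(cur$youden - best$youden) <= 1e-12 &&
           cur$specificity > best$specificity + 1e-12))
        best <- cur
    }
  }
  auc <- rocAUC(scores, labels)
  best$auc <- if (best$orientation == ">=") auc else 1 - auc
  best$youden <- NULL
  best
}

#' Build a train-test sampling plan
#'
#' Three schemes: leave-one-out (n singleton test folds), stratified
#' k-fold cross-validation (class-balanced folds whose sizes differ by
#' at most one), and a single stratified percentage split at the given
#' training fraction. Deterministic given the seed.
#'
#' @param ids identifiers (any vector); folds index into it.
#' @param labels 0/1 labels aligned with \code{ids}.
#' @param scheme "loo", "kfold" or "percentage".
#' @param k folds for "kfold".
#' @param trainFraction training fraction for "percentage".
#' @param seed RNG seed.
#' @param stratified stratify folds by class (default TRUE).
#' @return A \linkS4class{SplitPlan}; folds hold integer positions into
#'   \code{ids}.
#' @export
makeSplits <- function(ids, labels, scheme = c("loo", "kfold", "percentage"),
                       k = 10, trainFraction = 0.5, seed = 1,
                       stratified = TRUE) {
  scheme <- match.arg(scheme)
  n <- length(ids)
  labels <- as.integer(labels)
  stopifnot(length(labels) == n)
  idx <- seq_len(n)
  if (scheme == "loo") {
    folds <- lapply(idx, function(i) list(train = idx[-i], test = i))
    label <- "leave_one_out"
  } else if (scheme == "kfold") {
    if (n < k) stop(sprintf("kfold(%d) needs at least %d cases", k, k))
    ord <- withr::with_seed(as.integer(seed), {
      if (stratified) unlist(lapply(split(idx, labels), sample),
                             use.names = FALSE)
      else sample(idx)
    })
    fold <- (seq_len(n) - 1L) %% as.integer(k) + 1L
    folds <- lapply(seq_len(k), function(f)
      list(train = sort(ord[fold != f]), test = sort(ord[fold == f])))
    label <- sprintf("kfold(%d)", as.integer(k))
  } else {
    stopifnot(trainFraction > 0, trainFraction < 1)
    train <- withr::with_seed(as.integer(seed), {
      if (stratified) {
        byClass <- split(idx, labels)
        sizes <- vapply(byClass, length, integer(1))
        take <- floor(trainFraction * sizes)
        ## distribute the remainder by largest fractional part
        rem <- round(trainFraction * n) - sum(take)
        if (rem > 0) {
          frac <- trainFraction * sizes - take
          take[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
            take[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
        }
        sort(unlist(mapply(function(v, t) sample(v, t), byClass, take,
                           SIMPLIFY = FALSE), use.names = FALSE))
      } else sort(sample(idx, round(trainFraction * n)))
    })
    folds <- list(list(train = train, test = setdiff(idx, train)))
    label <- sprintf("percentage(%.2f)", trainFraction)
  }
  for (f in folds)
    if (length(unique(labels[f$train])) < 2L)
      stop(paste("a training fold contains a single class;",
                 "use stratification or more cases"))
  new("SplitPlan", scheme = label, folds = folds, seed = as.integer(seed),
      stratified = stratified)
}

#' Summarize per-trial AUC values
#'
#' Arithmetic mean, sample SD (n - 1) and the coefficient of variation
#' CV = 100 SD / mean, rounded half-up to an integer percent and
#' computed from the unrounded mean and SD. For reporting, mean and SD
#' are rounded to two decimals. With a single trial the SD and CV are
#' undefined (NA); a zero mean leaves the CV undefined.
#'
#' @param aucs numeric vector of per-trial AUC values.
#' @return List with \code{mean}, \code{sd}, \code{cv_percent} (raw),
#'   and \code{mean_2dp}, \code{sd_2dp} (rounded for reporting).
#' @export
#' @examples
#' summarizeTrials(c(0.88, 0.92, 0.87, 0.96, 0.94))
summarizeTrials <- function(aucs) {
  stopifnot(length(aucs) >= 1, is.numeric(aucs))
  m <- mean(aucs)
  s <- if (length(aucs) >= 2) stats::sd(aucs) else NA_real_
  cv <- if (is.na(s)) NA_real_
        else if (m == 0) { warning("CV undefined: mean AUC is 0"); NA_real_ }
        else .roundHalfUp(100 * s / m)
  list(mean = m, sd = s, cv_percent = cv,
       mean_2dp = .roundHalfUp(m, 2),
       sd_2dp = if (is.na(s)) NA_real_ else .roundHalfUp(s, 2))
}

#' Run repeated train-test trials and summarize AUC stability
#'
#' For cross-validation schemes (leave-one-out, k-fold) each trial fits
#' the model on every training fold, pools the out-of-fold predicted
#' probabilities and computes a single AUC over them. For percentage
#' splits each trial fits once on the training part and scores the test
#' part. Trial t uses seed \code{baseSeed + t - 1}; MLP weight seeds are
#' derived from the trial seed, so the whole run is deterministic.
#'
#' @param ft feature-table SummarizedExperiment.
#' @param features predictor subset (default: all 16).
#' @param modelKind "logistic", "naive_bayes" or "mlp".
#' @param scheme,k,trainFraction see \code{\link{makeSplits}}.
#' @param nTrials number of repeated trials.
#' @param baseSeed seed of the first trial.
#' @param groupBySubject keep all images of a subject in the same side
#'   of every split (off by default: the image is the sampling unit).
#' @return A \linkS4class{TrialSummary}.
#' @export
runTrials <- function(ft, features = NULL,
                      modelKind = c("naive_bayes", "logistic", "mlp"),
                      scheme = c("loo", "kfold", "percentage"), k = 10,
                      trainFraction = 0.5, nTrials = 1, baseSeed = 1,
                      groupBySubject = FALSE) {
  modelKind <- match.arg(modelKind)
  scheme <- match.arg(scheme)
  d <- .designMatrix(ft, features)
  cd <- SummarizedExperiment::colData(ft)
  units <- if (groupBySubject) as.character(cd$subject_id)
           else as.character(cd$image_id)
  aucs <- numeric(nTrials)
  planLabel <- NULL
  for (t in seq_len(nTrials)) {
    trialSeed <- as.integer(baseSeed) + t - 1L
    uniq <- unique(units)
    uLab <- vapply(uniq, function(u)
      as.integer(round(mean(d$y[units == u]))), integer(1))
    plan <- makeSplits(uniq, uLab, scheme, k = k,
                       trainFraction = trainFraction, seed = trialSeed)
    planLabel <- plan@scheme
    mlpSeeds <- .subSeeds(trialSeed, length(plan@folds))
    pooled <- rep(NA_real_, nrow(d$X))
    testMask <- logical(nrow(d$X))
    for (fi in seq_along(plan@folds)) {
      f <- plan@folds[[fi]]
      trainRows <- which(units %in% uniq[f$train])
      testRows <- which(units %in% uniq[f$test])
      df <- as.data.frame(d$X[trainRows, , drop = FALSE])
      df$label <- d$y[trainRows]
      fit <- tryCatch(
        .fitModel(modelKind, df, colnames(d$X), seed = mlpSeeds[fi]),
        error = function(e) stop(sprintf(
          "trial %d, fold %d (%s): %s", t, fi, planLabel,
          conditionMessage(e)), call. = FALSE))
      pooled[testRows] <- predictProba(fit, d$X[testRows, , drop = FALSE])
      testMask[testRows] <- TRUE
    }
    aucs[t] <- rocAUC(pooled[testMask], d$y[testMask])
  }
  sm <- summarizeTrials(aucs)
  new("TrialSummary", scheme = planLabel, classifier = modelKind,
      aucs = aucs, meanAuc = sm$mean, sdAuc = sm$sd,
      cvPercent = if (is.na(sm$cv_percent)) NA_real_
                  else as.numeric(sm$cv_percent))
}

#' Per-feature diagnostic performance
#'
#' Evaluates every feature as a univariate score via
#' \code{\link{youdenThreshold}}: chosen orientation, threshold,
#' sensitivity, specificity and oriented AUC.
#'
#' @param ft feature-table SummarizedExperiment.
#' @return \link[S4Vectors]{DataFrame}, one row per feature.
#' @export
featurePerformance <- function(ft) {
  fl <- .ftMatrixLabels(ft)
  rows <- lapply(rownames(fl$m), function(f) {
    y <- youdenThreshold(fl$m[f, ], fl$lab)
    data.frame(feature = f, orientation = y$orientation,
               threshold = y$threshold, sensitivity = y$sensitivity,
               specificity = y$specificity, auc = y$auc)
  })
  S4Vectors::DataFrame(do.call(rbind, rows))
}
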