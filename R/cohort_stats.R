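## Group comparison and significance-based feature screening.

.ftMatrixLabels <- function(ft) {
  m <- SummarizedExperiment::assay(ft, "features")
  lab <- SummarizedExperiment::colData(ft)$label
  if (anyNA(lab)) stop("feature table contains unlabeled images")
  list(m = m, lab = lab)
}

#' Compare feature distributions between fibrosis classes
#'
#' Welch's unequal-variance two-sample t-test per feature (two-tailed p
#' via Welch-Satterthwaite degrees of freedom), comparing advanced
#' (label 1) against early (label 0) images. No multiple-testing
#' correction is applied; this is recorded in the result's metadata.
#'
#' @param ft feature-table SummarizedExperiment
#'   (\code{\link{extractFeatureTable}}).
#' @param alpha two-tailed significance level (default 0.05).
#' @return A \link[S4Vectors]{DataFrame} with one row per feature:
#'   group means and SDs, t statistic (advanced minus early), two-tailed
#'   p-value, significance flag, and the group sizes used; metadata
#'   records \code{alpha} and \code{correction = "none"}.
#' @export
groupCompare <- function(ft, alpha = 0.05) {
  fl <- .ftMatrixLabels(ft)
  n0 <- sum(fl$lab == 0); n1 <- sum(fl$lab == 1)
  if (n0 < 2 || n1 < 2)
    stop("both classes must be present with at least 2 images each")
  rows <- lapply(rownames(fl$m), function(f) {
    x0 <- fl$m[f, fl$lab == 0]; x1 <- fl$m[f, fl$lab == 1]
    if (stats::sd(x0) == 0 && stats::sd(x1) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(x1, x0, var.equal = FALSE)
    }
    data.frame(feature = f, early_mean = mean(x0), early_sd = stats::sd(x0),
               advanced_mean = mean(x1), advanced_sd = stats::sd(x1),
               t_statistic = unname(tt$statistic), p_value = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out$n_early <- n0
  out$n_advanced <- n1
  out <- S4Vectors::DataFrame(out)
  S4Vectors::metadata(out) <- list(alpha = alpha, correction = "none")
  out
}

#' Select significant features
#'
#' Returns the features flagged significant by \code{\link{groupCompare}}
#' in the canonical feature order; an empty selection is an error (the
#' significance level should be reviewed).
#'
#' @param comparison result of \code{\link{groupCompare}}.
#' @return Character vector of feature names.
#' @export
selectFeatures <- function(comparison) {
  if (!all(c("feature", "significant") %in% colnames(comparison)))
    stop("comparison must come from groupCompare()")
  sel <- comparison$feature[comparison$significant]
  sel <- .FEATURES[.FEATURES %in% sel]
  if (length(sel) == 0)
    stop(sprintf(
      "no feature significant at alpha = %s; review the significance level",
      format(S4Vectors::metadata(comparison)$alpha)))
  sel
}

#' Class means of min-max normalized features
#'
#' Rescales each feature's pooled per-image values to [0, 1] (min-max
#' over both classes together) and reports the class means of the
#' rescaled values, as used for normalized-scale bar charts. A constant
#' feature cannot be rescaled; both class means are set to 0.5 by
#' convention and the row is flagged.
#'
#' @param ft feature-table SummarizedExperiment.
#' @return \link[S4Vectors]{DataFrame} with columns \code{feature},
#'   \code{early}, \code{advanced}, \code{constant}.
#' @export
normalizedGroupMeans <- function(ft) {
  fl <- .ftMatrixLabels(ft)
  if (!all(c(0, 1) %in% fl$lab)) stop("both classes must be present")
  rows <- lapply(rownames(fl$m), function(f) {
    x <- fl$m[f, ]
    rng <- range(x)
    if (rng[1] == rng[2]) {
      data.frame(feature = f, early = 0.5, advanced = 0.5, constant = TRUE)
    } else {
      z <- (x - rng[1]) / (rng[2] - rng[1])
      data.frame(feature = f, early = mean(z[fl$lab == 0]),
                 advanced = mean(z[fl$lab == 1]), constant = FALSE)
    }
  })
  S4Vectors::DataFrame(do.call(rbind, rows))
}

#' Write a group-comparison report CSV
#'
#' One row per feature with numeric columns plus formatted
#' "mean +/- SD" summaries for each class, the p-value and the group
#' sizes actually used. A header comment records that no multiple-testing
#' correction was applied.
#'
#' @param comparison result of \code{\link{groupCompare}}.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeGroupComparison <- function(comparison, path) {
  df <- as.data.frame(comparison)
  df$early_summary <- sprintf("%.1f ± %.1f", df$early_mean, df$early_sd)
  df$advanced_summary <- sprintf("%.1f ± %.1f", df$advanced_mean,
                                 df$advanced_sd)
  md <- S4Vectors::metadata(comparison)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# alpha = %s; multiple-testing correction: %s",
                     format(md$alpha), md$correction), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Bar chart of normalized class means
#'
#' Paired bars (early vs advanced) of the min-max normalized feature
#' means, with significance asterisks taken from a group comparison.
#'
#' @param ngm result of \code{\link{normalizedGroupMeans}}.
#' @param comparison optional result of \code{\link{groupCompare}} used
#'   to mark significant features.
#' @param file optional PNG path; NULL plots to the active device.
#' @return Invisibly, the matrix of plotted heights.
#' @export
plotNormalizedMeans <- function(ngm, comparison = NULL, file = NULL) {
  hm <- t(as.matrix(as.data.frame(ngm)[, c("early", "advanced")]))
  labs <- unname(.FEATURE_ABBREV[ngm$feature])
  if (!is.null(comparison)) {
    sig <- comparison$significant[match(ngm$feature, comparison$feature)]
    labs <- paste0(labs, ifelse(isTRUE(sig) | sig %in% TRUE, "*", ""))
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 450)
    on.exit(grDevices::dev.off())
  }
  graphics::barplot(hm, beside = TRUE, names.arg = labs, las = 2,
                    col = c("orange", "steelblue"),
                    ylab = "normalized feature mean (0-1)",
                    legend.text = c("early", "advanced"),
                    args.legend = list(x = "topright", bty = "n"))
  invisible(hm)
}
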