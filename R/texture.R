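## Texture feature extraction: quantization, first-order statistics,
## gray-level co-occurrence (Haralick) and gray-level run-length features.

#' Min-max quantize a region of interest
#'
#' Maps ROI pixel values onto \code{levels} gray levels with the min-max
#' rule \code{level = floor((x - min) * levels / (max - min + 1))}. A
#' constant region maps entirely to level 0.
#'
#' @param image \linkS4class{LiverImage} or plain numeric matrix.
#' @param roi 0-based half-open rectangle \code{c(x0, y0, x1, y1)}, a
#'   single-row ROI data.frame, or NULL for the whole image.
#' @param levels number of gray levels Ng (>= 2).
#' @return A \linkS4class{QuantizedROI}.
#' @export
#' @examples
#' quantizeROI(matrix(0:255, 16), levels = 32)
quantizeROI <- function(image, roi = NULL, levels = 32) {
  m <- .roiPixels(image, roi)
  if (length(m) == 0) stop("empty ROI")
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  mn <- min(m); mx <- max(m)
  q <- floor((m - mn) * levels / (mx - mn + 1))
  storage.mode(q) <- "integer"
  new("QuantizedROI", levels = levels, grid = q,
      nPixels = as.integer(length(q)))
}

#' First-order (histogram) features of a region
#'
#' Echo intensity is the ROI pixel mean, heterogeneity the sample SD
#' (n - 1 denominator). Skewness and kurtosis use central sample moments
#' m_k: skewness = m3 / m2^1.5 and kurtosis = m4 / m2^2 - 3 (excess,
#' Fisher convention); both are defined as 0 for a constant region.
#'
#' @inheritParams quantizeROI
#' @return Named numeric vector: \code{echo_intensity},
#'   \code{heterogeneity}, \code{skewness}, \code{kurtosis}.
#' @export
firstOrderFeatures <- function(image, roi = NULL) {
  x <- as.numeric(.roiPixels(image, roi))
  n <- length(x)
  if (n < 4) stop("ROI must contain at least 4 pixels")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 == 0) {
    sk <- 0; ku <- 0
  } else {
    sk <- mean(d^3) / m2^1.5
    ku <- mean(d^4) / m2^2 - 3
  }
  c(echo_intensity = mu, heterogeneity = stats::sd(x),
    skewness = sk, kurtosis = ku)
}

## (row, col) pixel offsets for a co-occurrence / run direction.
## 0 deg is horizontal (along a row); 45/90/135 rotate counter-clockwise.
.dirOffset <- function(angle, d = 1L) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L),
         "135" = c(-d, -d),
         stop("supported directions: 0, 45, 90, 135 degrees"))
}

#' Gray-level co-occurrence matrix
#'
#' Counts pairs of gray levels at pixel offset \code{distance} along each
#' requested direction (both pixels inside the region), pools the counts
#' over directions, optionally adds the transpose (symmetric form), and
#' normalizes to joint probabilities.
#'
#' @param qroi a \linkS4class{QuantizedROI}.
#' @param distance offset length in pixels (>= 1).
#' @param directions angles in degrees, subset of {0, 45, 90, 135}.
#' @param symmetric add the transposed counts before normalization.
#' @return A \linkS4class{GLCMatrix}.
#' @export
computeGLCM <- function(qroi, distance = 1, directions = c(0, 45, 90, 135),
                        symmetric = TRUE) {
  stopifnot(is(qroi, "QuantizedROI"), distance >= 1)
  g <- qroi@grid
  ng <- qroi@levels
  d <- as.integer(distance)
  h <- nrow(g); w <- ncol(g)
  counts <- matrix(0, ng, ng)
  for (ang in directions) {
    off <- .dirOffset(ang, d)
    rlo <- max(1L, 1L - off[1]); rhi <- min(h, h - off[1])
    clo <- max(1L, 1L - off[2]); chi <- min(w, w - off[2])
    if (rlo > rhi || clo > chi) next
    r1 <- rlo:rhi; c1 <- clo:chi
    a <- g[r1, c1, drop = FALSE]
    b <- g[r1 + off[1], c1 + off[2], drop = FALSE]
    counts <- counts + matrix(
      tabulate(as.vector(a) * ng + as.vector(b) + 1L, nbins = ng * ng),
      ng, ng, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot == 0)
    stop("region too small for this distance in every direction: no pairs")
  new("GLCMatrix", P = counts / tot, distance = as.numeric(distance),
      directions = as.numeric(directions), symmetric = symmetric)
}

#' Haralick features of a co-occurrence matrix
#'
#' With P(i, j) the joint probabilities over gray levels i, j = 0..Ng-1
#' and Px the row marginal: ASM = sum P^2; contrast = sum (i-j)^2 P;
#' dissimilarity = sum |i-j| P; entropy = -sum P log P (natural log, over
#' P > 0); GLCM mean = sum i Px(i); GLCM variance = sum (i - mu_x)^2
#' Px(i); GLCM correlation = sum (i - mu_x)(j - mu_y) P / (sigma_x
#' sigma_y), defined as 0 when either marginal SD vanishes.
#'
#' @param glcm a \linkS4class{GLCMatrix}.
#' @return Named numeric vector of the seven co-occurrence features.
#' @export
glcmFeatures <- function(glcm) {
  stopifnot(is(glcm, "GLCMatrix"))
  P <- glcm@P
  ng <- nrow(P)
  lev <- 0:(ng - 1)
  ii <- matrix(lev, ng, ng)
  jj <- t(ii)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(lev * px); muy <- sum(lev * py)
  vx <- sum((lev - mux)^2 * px); vy <- sum((lev - muy)^2 * py)
  pos <- P > 0
  corr <- if (vx > 0 && vy > 0)
    sum((ii - mux) * (jj - muy) * P) / sqrt(vx * vy) else 0
  c(asm = sum(P^2),
    contrast = sum((ii - jj)^2 * P),
    dissimilarity = sum(abs(ii - jj) * P),
    entropy = -sum(P[pos] * log(P[pos])),
    glcm_mean = mux,
    glcm_variance = vx,
    glcm_correlation = corr)
}

#' Gray-level run-length matrix
#'
#' Decomposes every line of the region, in every requested direction,
#' into maximal runs of constant gray level and accumulates the counts
#' r(i, j) of runs of level i and length j. Diagonal directions use the
#' region's diagonals and anti-diagonals as lines.
#'
#' @param qroi a \linkS4class{QuantizedROI}.
#' @param directions angles in degrees, subset of {0, 45, 90, 135}.
#' @return A \linkS4class{RunLengthMatrix}.
#' @export
computeRLM <- function(qroi, directions = c(0, 45, 90, 135)) {
  stopifnot(is(qroi, "QuantizedROI"), length(directions) >= 1)
  g <- qroi@grid
  ng <- qroi@levels
  lmax <- max(nrow(g), ncol(g))
  counts <- matrix(0L, ng, lmax)
  for (ang in directions) {
    lines <- switch(as.character(ang),
      "0" = split(g, row(g)),
      "90" = split(g, col(g)),
      "45" = split(g, row(g) + col(g)),    # anti-diagonals
      "135" = split(g, row(g) - col(g)),   # main diagonals
      stop("supported directions: 0, 45, 90, 135 degrees"))
    runs <- lapply(lines, function(v) rle(as.vector(v)))
    levs <- unlist(lapply(runs, `[[`, "values"), use.names = FALSE)
    lens <- unlist(lapply(runs, `[[`, "lengths"), use.names = FALSE)
    ## column-major index into the Ng x Lmax count matrix
    counts <- counts + matrix(
      tabulate((lens - 1L) * ng + levs + 1L, nbins = ng * lmax), ng, lmax)
  }
  new("RunLengthMatrix", counts = counts, nRuns = as.integer(sum(counts)),
      nPixels = qroi@nPixels, directions = as.numeric(directions))
}

#' Run-length features
#'
#' With r(i, j) the run counts, Nr the total number of runs, Np the
#' pixel count and D the number of directions: SRE = (1/Nr) sum r/j^2;
#' LRE = (1/Nr) sum r j^2; GLN = (1/Nr^2) sum_i (sum_j r)^2; RLN =
#' (1/Nr^2) sum_j (sum_i r)^2; run percentage RP = Nr / (Np D). The
#' squared-probability normalization of GLN/RLN keeps both in (0, 1].
#'
#' @param rlm a \linkS4class{RunLengthMatrix}.
#' @return Named numeric vector of the five run-length features.
#' @export
rlmFeatures <- function(rlm) {
  stopifnot(is(rlm, "RunLengthMatrix"))
  r <- rlm@counts
  nr <- rlm@nRuns
  if (nr < 1) stop("run-length matrix holds no runs")
  j2 <- (seq_len(ncol(r)))^2
  rowTot <- rowSums(r); colTot <- colSums(r)
  c(short_run = sum(sweep(r, 2, j2, "/")) / nr,
    long_run = sum(sweep(r, 2, j2, "*")) / nr,
    gl_nonuniformity = sum(rowTot^2) / nr^2,
    rl_nonuniformity = sum(colTot^2) / nr^2,
    run_percentage = nr / (rlm@nPixels * length(rlm@directions)))
}

## all 16 features of one ROI, in canonical order
.roiFeatures <- function(image, roi, levels, distance, directions,
                         symmetric) {
  fo <- firstOrderFeatures(image, roi)
  q <- quantizeROI(image, roi, levels)
  rl <- rlmFeatures(computeRLM(q, directions))
  gl <- glcmFeatures(computeGLCM(q, distance, directions, symmetric))
  c(fo, rl, gl)[.FEATURES]
}

#' Extract the 16-feature table of a cohort
#'
#' Computes all 16 texture features for every ROI of every image and
#' aggregates ROI vectors to one per-image vector by unweighted mean (the
#' image is the statistical unit). The result is a
#' \link[SummarizedExperiment]{SummarizedExperiment} with one assay
#' \code{"features"} (16 features x images) and column metadata
#' \code{image_id}, \code{subject_id}, \code{label}.
#'
#' @param cohort list of \code{list(image = LiverImage, rois = ROISet)},
#'   as produced by \code{\link{generateCohort}} or
#'   \code{\link{loadExternalCohort}}.
#' @param levels gray levels for quantization (default 32).
#' @param distance co-occurrence offset in pixels (default 1).
#' @param directions angles in degrees (default 0, 45, 90, 135).
#' @param symmetric symmetric co-occurrence counting (default TRUE).
#' @return A SummarizedExperiment; extraction parameters are stored in
#'   its metadata.
#' @export
extractFeatureTable <- function(cohort, levels = 32, distance = 1,
                                directions = c(0, 45, 90, 135),
                                symmetric = TRUE) {
  .cohortCheck(cohort)
  mats <- lapply(cohort, function(e) {
    rois <- e$rois@rois
    if (nrow(rois) < 1L) stop("every image needs at least one ROI")
    per <- vapply(seq_len(nrow(rois)), function(k)
      .roiFeatures(e$image, unlist(rois[k, c("x0", "y0", "x1", "y1")]),
                   levels, distance, directions, symmetric),
      numeric(length(.FEATURES)))
    rowMeans(per)
  })
  m <- do.call(cbind, mats)
  rownames(m) <- .FEATURES
  ids <- vapply(cohort, function(e) e$image@acquisitionId, character(1))
  ids[is.na(ids)] <- sprintf("img%03d", which(is.na(ids)))
  cd <- S4Vectors::DataFrame(
    image_id = ids,
    subject_id = vapply(cohort, function(e) e$image@subjectId,
                        character(1)),
    label = vapply(cohort, function(e) e$image@label, integer(1)))
  colnames(m) <- cd$image_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = m), colData = cd,
    metadata = list(levels = levels, distance = distance,
                    directions = directions, symmetric = symmetric))
}

#' Write a feature table CSV
#'
#' One row per image with columns \code{image_id}, \code{subject_id},
#' \code{label}, then the 16 features under their two-letter
#' abbreviations, in canonical order.
#'
#' @param ft feature-table SummarizedExperiment.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeFeatureTable <- function(ft, path) {
  m <- t(SummarizedExperiment::assay(ft, "features"))
  colnames(m) <- unname(.FEATURE_ABBREV[colnames(m)])
  cd <- SummarizedExperiment::colData(ft)
  df <- data.frame(image_id = cd$image_id, subject_id = cd$subject_id,
                   label = cd$label, check.names = FALSE)
  df <- cbind(df, as.data.frame(signif(m, 10)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
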