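## Cohort-level simulation: ROI grids, two-class cohorts, calibration.

#' Place a default grid of square ROIs on an image
#'
#' Lays out \code{nRois} non-overlapping square ROIs of side
#' \code{roiSize} on a grid that keeps an 8-pixel margin from the image
#' border. When a seed is supplied each ROI is jittered within its grid
#' cell; without a seed the grid is deterministic (cell-centered). This
#' stands in for the manual outlining of representative parenchymal
#' regions.
#'
#' @param image a \linkS4class{LiverImage}.
#' @param nRois number of ROIs (1--6).
#' @param roiSize side length in pixels.
#' @param seed optional RNG seed for jitter.
#' @param margin border margin in pixels.
#' @return An \linkS4class{ROISet} with 0-based half-open rectangles.
#' @export
#' @examples
#' img <- simulateSpeckleField(256, 256, 2, 40, 15, seed = 1)
#' defaultRoiGrid(img, 5, 64)
defaultRoiGrid <- function(image, nRois = 5, roiSize = 64, seed = NULL,
                           margin = 8) {
  p <- if (is(image, "LiverImage")) image@pixels else image
  h <- nrow(p); w <- ncol(p)
  nRois <- as.integer(nRois); roiSize <- as.integer(roiSize)
  nx <- (w - 2L * margin) %/% roiSize
  ny <- (h - 2L * margin) %/% roiSize
  if (nx < 1L || ny < 1L || nRois > nx * ny)
    stop(sprintf(
      "cannot fit %d ROIs of %dx%d in a %dx%d image (max feasible: %d)",
      nRois, roiSize, roiSize, h, w, max(0L, nx * ny)))
  cellW <- (w - 2L * margin) %/% nx
  cellH <- (h - 2L * margin) %/% ny
  cells <- expand.grid(cx = seq_len(nx), cy = seq_len(ny))
  ## spread the chosen cells over the grid rather than clustering top-left
  ord <- order(seq_len(nrow(cells)) %% max(1L, nrow(cells) %/% nRois),
               cells$cy, cells$cx)
  cells <- cells[ord[seq_len(nRois)], , drop = FALSE]
  slackX <- cellW - roiSize; slackY <- cellH - roiSize
  if (!is.null(seed)) {
    j <- withr::with_seed(as.integer(seed), {
      cbind(floor(stats::runif(nRois, 0, slackX + 1)),
            floor(stats::runif(nRois, 0, slackY + 1)))
    })
  } else {
    j <- cbind(rep(slackX %/% 2L, nRois), rep(slackY %/% 2L, nRois))
  }
  x0 <- margin + (cells$cx - 1L) * cellW + as.integer(j[, 1])
  y0 <- margin + (cells$cy - 1L) * cellH + as.integer(j[, 2])
  ROISet(imageRef = if (is(image, "LiverImage")) image@acquisitionId
                    else NA_character_,
         rois = data.frame(x0 = x0, y0 = y0,
                           x1 = x0 + roiSize, y1 = y0 + roiSize))
}

## Draw the per-image first-order targets of one class. The Gaussian
## jitter is centered and rescaled so the finite cohort hits the class
## mean and between-image SD exactly (not just in expectation); the
## per-image feasibility clamps keep 8-bit clipping mild and introduce a
## small systematic bias that the calibration gains absorb.
.drawClassTargets <- function(n, echoMean, echoSd, hetMean, hetSd) {
  e <- stats::rnorm(n); h <- stats::rnorm(n)
  if (n >= 2) {
    e <- (e - mean(e)) / max(stats::sd(e), 1e-12)
    h <- (h - mean(h)) / max(stats::sd(h), 1e-12)
  } else {
    e <- 0; h <- 0
  }
  echo <- pmin(pmax(echoMean + echoSd * e, 5), 250)
  het <- pmin(pmax(hetMean + hetSd * h, 0.5), echo / 1.8)
  cbind(echo = echo, het = het)
}

#' Generate a labeled two-class synthetic cohort
#'
#' Produces \code{nEarly} early-fibrosis and \code{nAdvanced}
#' advanced-fibrosis images. Per-image echo-intensity / heterogeneity
#' targets are drawn from the class-wise Gaussians of the configuration
#' (multiplied by the calibration gains), so the cohort reproduces both
#' the class means and the between-image spreads of the modeled data.
#' Advanced images additionally receive a collagen-septa overlay
#' (\code{\link{addSeptae}}); early images get none. Subjects contribute
#' \code{imagesPerSubject} consecutive images each, and every image gets
#' a default jittered ROI grid. Fully deterministic given the seed.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param nEarly,nAdvanced images per class (>= 0, at least one total).
#' @param imagesPerSubject images contributed by each subject.
#' @param seed master seed for the cohort.
#' @return A list with one element per image:
#'   \code{list(image = LiverImage, rois = ROISet)}.
#' @export
generateCohort <- function(config = simulationConfig(), nEarly = 100,
                           nAdvanced = 100, imagesPerSubject = 5,
                           seed = config@seed) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  nEarly <- as.integer(nEarly); nAdvanced <- as.integer(nAdvanced)
  n <- nEarly + nAdvanced
  if (n < 1L) stop("need at least one image")
  allSeeds <- .subSeeds(seed, 3L * n + 2L)
  seeds <- matrix(allSeeds[seq_len(3L * n)], ncol = 3L)
  g <- config@gains
  targets <- rbind(
    if (nEarly > 0) withr::with_seed(allSeeds[3L * n + 1L],
      .drawClassTargets(nEarly, config@earlyEchoTarget * g[1],
                        config@earlyEchoSd,
                        config@earlyHetTarget * g[2], config@earlyHetSd)),
    if (nAdvanced > 0) withr::with_seed(allSeeds[3L * n + 2L],
      .drawClassTargets(nAdvanced, config@advancedEchoTarget * g[3],
                        config@advancedEchoSd,
                        config@advancedHetTarget * g[4],
                        config@advancedHetSd)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    early <- i <= nEarly
    idx <- if (early) i else i - nEarly
    subj <- sprintf("%s%03d", if (early) "E" else "A",
                    (idx - 1L) %/% as.integer(imagesPerSubject) + 1L)
    acq <- sprintf("%s_img%03d", subj,
                   (idx - 1L) %% as.integer(imagesPerSubject) + 1L)
    tg <- targets[i, ]
    img <- simulateSpeckleField(config@imageHeight, config@imageWidth,
                                config@psfSigma, tg["echo"], tg["het"],
                                seed = seeds[i, 1],
                                label = if (early) 0L else 1L,
                                subjectId = subj, acquisitionId = acq)
    if (!early && config@septaDensity > 0)
      img <- addSeptae(img, config@septaDensity, config@septaBrightness,
                       config@septaThickness, seed = seeds[i, 2])
    rois <- defaultRoiGrid(img, config@nRois, config@roiSize,
                           seed = seeds[i, 3])
    out[[i]] <- list(image = img, rois = rois)
  }
  out
}

#' Calibrate the generator against extracted feature targets
#'
#' The raw pixel moments of a simulated image are not identical to the
#' extracted ROI feature means (ROI averaging, clipping and the septa
#' overlay all shift them), so the generator carries multiplicative gain
#' corrections on its per-class targets. This routine iterates: simulate
#' a small pilot cohort, extract the 16 features, compare the class means
#' of echo intensity and heterogeneity with the targets, and update the
#' four gains multiplicatively until all four relative errors fall below
#' \code{tolerance}.
#'
#' @param config starting \linkS4class{SimulationConfig}; its target
#'   slots define the calibration targets.
#' @param tolerance relative tolerance in (0, 0.2].
#' @param seed seed for the pilot cohorts.
#' @param pilotN pilot images per class.
#' @param maxIter iteration cap; exceeding it raises a
#'   calibration-failure error carrying the best configuration so far.
#' @return The calibrated \linkS4class{SimulationConfig}; the
#'   \code{achieved} slot records the achieved feature means, the
#'   iteration count and the tolerance.
#' @export
calibrateGenerator <- function(config = simulationConfig(),
                               tolerance = 0.05, seed = 1, pilotN = 10,
                               maxIter = 12) {
  stopifnot(is(config, "SimulationConfig"))
  if (tolerance <= 0 || tolerance > 0.2)
    stop("tolerance must lie in (0, 0.2]")
  targets <- c(config@earlyEchoTarget, config@earlyHetTarget,
               config@advancedEchoTarget, config@advancedHetTarget)
  if (any(targets <= 0) || any(targets >= 255))
    stop("calibration failure: targets outside the 8-bit range (0, 255)")
  best <- NULL; bestErr <- Inf
  for (it in seq_len(maxIter)) {
    pilot <- generateCohort(config, pilotN, pilotN,
                            imagesPerSubject = pilotN, seed = seed)
    ft <- extractFeatureTable(pilot)
    m <- SummarizedExperiment::assay(ft)
    lab <- SummarizedExperiment::colData(ft)$label
    ach <- c(mean(m["echo_intensity", lab == 0]),
             mean(m["heterogeneity", lab == 0]),
             mean(m["echo_intensity", lab == 1]),
             mean(m["heterogeneity", lab == 1]))
    relErr <- abs(ach - targets) / targets
    if (max(relErr) < bestErr) {
      bestErr <- max(relErr)
      best <- list(config = config, achieved = ach, iteration = it)
    }
    if (all(relErr <= tolerance)) {
      config@achieved <- list(
        earlyEcho = ach[1], earlyHet = ach[2],
        advancedEcho = ach[3], advancedHet = ach[4],
        iterations = it, tolerance = tolerance)
      return(config)
    }
    config@gains <- config@gains * (targets / ach)
  }
  stop(sprintf(paste0(
    "calibration failure: no convergence in %d iterations ",
    "(best max relative error %.3f; best gains: %s)"),
    maxIter, bestErr, paste(sprintf("%.3f", best$config@gains),
                            collapse = " ")))
}
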