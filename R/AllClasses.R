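#' @import methods
NULL

## Canonical order of the 16 texture features; used everywhere a feature
## vector or table is assembled.
.FEATURES <- c(
  "echo_intensity", "heterogeneity", "kurtosis", "skewness",
  "short_run", "long_run", "gl_nonuniformity", "rl_nonuniformity",
  "run_percentage",
  "asm", "contrast", "dissimilarity", "entropy",
  "glcm_mean", "glcm_variance", "glcm_correlation"
)

.FEATURE_ABBREV <- c(
  echo_intensity = "EI", heterogeneity = "HT", kurtosis = "KT",
  skewness = "SK", short_run = "SR", long_run = "LR",
  gl_nonuniformity = "GU", rl_nonuniformity = "RU", run_percentage = "R%",
  asm = "AM", contrast = "CT", dissimilarity = "DS", entropy = "ET",
  glcm_mean = "GM", glcm_variance = "GV", glcm_correlation = "GC"
)

#' Names and abbreviations of the 16 texture features
#'
#' The fixed, canonical ordering of the texture feature set: four
#' first-order features (echo intensity, heterogeneity, kurtosis,
#' skewness), five run-length features and seven co-occurrence (Haralick)
#' features. \code{featureAbbreviations} returns the two-letter column
#' labels used in exported CSV reports.
#'
#' @return A character vector of length 16.
#' @export
#' @examples
#' textureFeatureNames()
textureFeatureNames <- function() .FEATURES

#' @rdname textureFeatureNames
#' @export
featureAbbreviations <- function() .FEATURE_ABBREV

## ---------------------------------------------------------------------------
## LiverImage

#' LiverImage: an 8-bit grayscale B-mode-like image
#'
#' Container for a single 2D ultrasound B-mode (or simulated B-mode) image
#' of liver parenchyma: an integer pixel grid in [0, 255], an optional
#' fibrosis class label (0 = early, F0--1; 1 = advanced, F2--4;
#' \code{NA} = unlabeled) and subject / acquisition identifiers.
#'
#' @slot pixels integer matrix, values in 0..255, at least 64 x 64.
#' @slot label integer scalar: 0, 1 or NA.
#' @slot subjectId,acquisitionId character identifiers.
#'
#' @aliases LiverImage
#' @exportClass LiverImage
setClass("LiverImage",
  representation(pixels = "matrix", label = "integer",
                 subjectId = "character", acquisitionId = "character"),
  prototype(label = NA_integer_, subjectId = NA_character_,
            acquisitionId = NA_character_))

setValidity("LiverImage", function(object) {
  p <- object@pixels
  msg <- character(0)
  if (nrow(p) < 64L || ncol(p) < 64L)
    msg <- c(msg, "image must be at least 64 x 64 pixels")
  if (anyNA(p) || any(p < 0) || any(p > 255))
    msg <- c(msg, "pixel values must lie in [0, 255]")
  if (any(p != round(p)))
    msg <- c(msg, "pixel values must be integral")
  if (length(object@label) != 1L ||
      (!is.na(object@label) && !object@label %in% c(0L, 1L)))
    msg <- c(msg, "label must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a LiverImage
#'
#' @param pixels numeric or integer matrix of gray levels in [0, 255].
#' @param label class label: 0 (early fibrosis), 1 (advanced) or NA.
#' @param subjectId,acquisitionId identifiers carried through the analysis.
#' @return A \linkS4class{LiverImage}.
#' @export
LiverImage <- function(pixels, label = NA, subjectId = NA_character_,
                       acquisitionId = NA_character_) {
  storage.mode(pixels) <- "integer"
  new("LiverImage", pixels = pixels, label = as.integer(label),
      subjectId = as.character(subjectId),
      acquisitionId = as.character(acquisitionId))
}

## ---------------------------------------------------------------------------
## ROISet

#' ROISet: rectangular regions of interest on one image
#'
#' Rectangles are stored 0-based, half-open: a ROI covers pixel columns
#' \code{x0..x1-1} and rows \code{y0..y1-1}. Between 1 and 6 ROIs per
#' image, each of area at least 256 pixels, mirroring the five-to-six
#' parenchymal regions outlined per image in practice.
#'
#' @slot imageRef character id of the image the ROIs refer to.
#' @slot rois data.frame with integer columns x0, y0, x1, y1.
#' @aliases ROISet
#' @exportClass ROISet
setClass("ROISet",
  representation(imageRef = "character", rois = "data.frame"))

setValidity("ROISet", function(object) {
  r <- object@rois
  msg <- character(0)
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(r)))
    return("rois must have columns x0, y0, x1, y1")
  if (nrow(r) < 1L || nrow(r) > 6L)
    msg <- c(msg, "between 1 and 6 ROIs per image")
  if (any(r$x1 <= r$x0) || any(r$y1 <= r$y0) || any(r$x0 < 0) || any(r$y0 < 0))
    msg <- c(msg, "ROI rectangles must be non-empty with non-negative origin")
  if (any((r$x1 - r$x0) * (r$y1 - r$y0) < 256))
    msg <- c(msg, "ROI area must be at least 256 pixels")
  if (length(msg)) msg else TRUE
})

#' @rdname ROISet-class
#' @param imageRef image identifier.
#' @param rois data.frame of 0-based half-open rectangles (x0, y0, x1, y1).
#' @export
ROISet <- function(imageRef, rois) {
  rois <- as.data.frame(rois)
  for (cc in c("x0", "y0", "x1", "y1")) rois[[cc]] <- as.integer(rois[[cc]])
  rownames(rois) <- NULL
  new("ROISet", imageRef = as.character(imageRef), rois = rois)
}

## ---------------------------------------------------------------------------
## SimulationConfig

#' SimulationConfig: parameters of the two-class speckle simulator
#'
#' Holds the image geometry, the point-spread (speckle correlation) scale,
#' the first-order calibration targets of the two fibrosis classes --
#' echo intensity (ROI mean gray level) and heterogeneity (ROI SD) with
#' their between-image spreads -- and the collagen-septa overlay
#' parameters used for the advanced class. The default targets are the
#' reference group moments of the modeled rat cohort (early: 35.7 +/- 9.0
#' and 16.9 +/- 2.9; advanced: 56.8 +/- 10.2 and 22.5 +/- 2.6 gray
#' levels). A single \code{psfSigma} is shared by both classes so that
#' the co-occurrence contrast of the two classes stays matched.
#'
#' The \code{gains} slot carries multiplicative corrections (early echo,
#' early het, advanced echo, advanced het) applied to the raw per-image
#' generation targets; \code{\link{calibrateGenerator}} adjusts them so
#' that the class means of the *extracted* features hit the targets.
#'
#' @aliases SimulationConfig
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(
    imageHeight = "integer", imageWidth = "integer", psfSigma = "numeric",
    earlyEchoTarget = "numeric", earlyHetTarget = "numeric",
    advancedEchoTarget = "numeric", advancedHetTarget = "numeric",
    earlyEchoSd = "numeric", earlyHetSd = "numeric",
    advancedEchoSd = "numeric", advancedHetSd = "numeric",
    septaDensity = "numeric", septaBrightness = "numeric",
    septaThickness = "numeric",
    nRois = "integer", roiSize = "integer",
    seed = "integer", gains = "numeric", achieved = "list"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  tg <- c(object@earlyEchoTarget, object@earlyHetTarget,
          object@advancedEchoTarget, object@advancedHetTarget)
  if (any(tg <= 0) || any(tg >= 255))
    msg <- c(msg, "all calibration targets must lie in (0, 255)")
  if (object@psfSigma < 0.5)
    msg <- c(msg, "psfSigma must be >= 0.5")
  if (object@septaDensity < 0)
    msg <- c(msg, "septaDensity must be >= 0")
  if (object@imageHeight < 64L || object@imageWidth < 64L)
    msg <- c(msg, "image must be at least 64 x 64")
  if (length(object@gains) != 4L || any(object@gains <= 0))
    msg <- c(msg, "gains must be 4 positive multipliers")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param imageHeight,imageWidth image size in pixels.
#' @param psfSigma Gaussian point-spread sigma in pixels (speckle
#'   correlation length); identical for both classes by design.
#' @param earlyEchoTarget,earlyHetTarget,advancedEchoTarget,advancedHetTarget
#'   class-wise targets for the extracted echo-intensity (mean gray) and
#'   heterogeneity (SD gray) feature means.
#' @param earlyEchoSd,earlyHetSd,advancedEchoSd,advancedHetSd between-image
#'   standard deviations of the per-image targets (gray levels).
#' @param septaDensity expected number of septal strokes per advanced image
#'   (Poisson); early images get none.
#' @param septaBrightness peak additive brightness of a septal stroke.
#' @param septaThickness stroke thickness in pixels.
#' @param nRois,roiSize default ROI grid: number and side length of square
#'   ROIs per image.
#' @param seed default master seed.
#' @param gains internal multiplicative calibration corrections; see
#'   \code{\link{calibrateGenerator}}.
#' @return A validated \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(imageHeight = 256L, imageWidth = 256L,
    psfSigma = 2.5,
    earlyEchoTarget = 35.7, earlyHetTarget = 16.9,
    advancedEchoTarget = 56.8, advancedHetTarget = 22.5,
    earlyEchoSd = 9.0, earlyHetSd = 2.9,
    advancedEchoSd = 10.2, advancedHetSd = 2.6,
    septaDensity = 8, septaBrightness = 63, septaThickness = 1.5,
    nRois = 5L, roiSize = 64L, seed = 7L,
    gains = c(1, 1, 1, 1)) {
  new("SimulationConfig",
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      psfSigma = psfSigma,
      earlyEchoTarget = earlyEchoTarget, earlyHetTarget = earlyHetTarget,
      advancedEchoTarget = advancedEchoTarget,
      advancedHetTarget = advancedHetTarget,
      earlyEchoSd = earlyEchoSd, earlyHetSd = earlyHetSd,
      advancedEchoSd = advancedEchoSd, advancedHetSd = advancedHetSd,
      septaDensity = septaDensity, septaBrightness = septaBrightness,
      septaThickness = septaThickness,
      nRois = as.integer(nRois), roiSize = as.integer(roiSize),
      seed = as.integer(seed), gains = gains, achieved = list())
}

## ---------------------------------------------------------------------------
## Quantized ROI / GLCM / RLM

#' QuantizedROI: a gray-level-quantized region
#'
#' @slot levels number of gray levels Ng (>= 2).
#' @slot grid integer matrix with values in 0..Ng-1.
#' @slot nPixels number of pixels in the region.
#' @aliases QuantizedROI
#' @exportClass QuantizedROI
setClass("QuantizedROI",
  representation(levels = "integer", grid = "matrix", nPixels = "integer"))

setValidity("QuantizedROI", function(object) {
  msg <- character(0)
  if (object@levels < 2L) msg <- c(msg, "levels must be >= 2")
  if (any(object@grid < 0L) || any(object@grid >= object@levels))
    msg <- c(msg, "all cells must lie in [0, levels - 1]")
  if (length(msg)) msg else TRUE
})

#' GLCMatrix: normalized gray-level co-occurrence matrix
#'
#' Joint probabilities P(i, j) of gray-level pairs at a fixed pixel
#' offset, pooled over the requested directions before normalization.
#' Row/column indices correspond to gray levels 0..Ng-1.
#'
#' @slot P Ng x Ng matrix of probabilities summing to 1.
#' @slot distance offset length in pixels.
#' @slot directions angles in degrees.
#' @slot symmetric whether the transpose was added before normalizing.
#' @aliases GLCMatrix
#' @exportClass GLCMatrix
setClass("GLCMatrix",
  representation(P = "matrix", distance = "numeric",
                 directions = "numeric", symmetric = "logical"))

setValidity("GLCMatrix", function(object) {
  msg <- character(0)
  if (any(object@P < 0)) msg <- c(msg, "probabilities must be non-negative")
  if (abs(sum(object@P) - 1) > 1e-9) msg <- c(msg, "probabilities must sum to 1")
  if (isTRUE(object@symmetric) &&
      max(abs(object@P - t(object@P))) > 1e-12)
    msg <- c(msg, "symmetric GLCM must equal its transpose")
  if (length(msg)) msg else TRUE
})

#' RunLengthMatrix: gray-level run-length counts
#'
#' Element r(i, j) counts maximal runs of gray level i-1 (0-based level
#' i-1) of length j, accumulated over the requested directions. A run is
#' a set of consecutive, collinear pixels sharing one gray level; its
#' length is the number of pixels in it.
#'
#' @slot counts Ng x Lmax integer matrix of run counts.
#' @slot nRuns total number of runs.
#' @slot nPixels number of pixels in the region.
#' @slot directions angles in degrees.
#' @aliases RunLengthMatrix
#' @exportClass RunLengthMatrix
setClass("RunLengthMatrix",
  representation(counts = "matrix", nRuns = "integer",
                 nPixels = "integer", directions = "numeric"))

setValidity("RunLengthMatrix", function(object) {
  msg <- character(0)
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "run counts must be non-negative integers")
  if (sum(object@counts) != object@nRuns)
    msg <- c(msg, "counts must sum to nRuns")
  if (object@nRuns > object@nPixels * length(object@directions))
    msg <- c(msg, "cannot have more runs than pixels x directions")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Trained models

#' TrainedModel and its subclasses
#'
#' Virtual parent of the three diagnostic models. Every model stores the
#' ordered feature subset it was fitted on and the training-fold
#' standardization constants (mean, SD per feature) applied before
#' prediction, and yields a probability of advanced fibrosis (class 1)
#' through \code{\link{predictProba}}.
#'
#' @slot kind "logistic", "naive_bayes" or "mlp".
#' @slot featureNames ordered character vector of predictors.
#' @slot center,scale standardization constants (training data).
#' @aliases TrainedModel
#' @exportClass TrainedModel
setClass("TrainedModel",
  representation(kind = "character", featureNames = "character",
                 center = "numeric", scale = "numeric", "VIRTUAL"))

setValidity("TrainedModel", function(object) {
  if (length(object@featureNames) < 1L)
    return("featureNames must be non-empty")
  TRUE
})

#' @slot coefficients coefficients on the standardized scale, intercept
#'   first.
#' @slot converged,iterations Newton iteration diagnostics.
#' @slot separation TRUE when quasi-complete separation was detected and
#'   the ridge-stabilized solution returned.
#' @rdname TrainedModel-class
#' @aliases LogisticModel
#' @exportClass LogisticModel
setClass("LogisticModel", contains = "TrainedModel",
  representation(coefficients = "numeric", converged = "logical",
                 iterations = "integer", separation = "logical"))

#' @slot priors class prior probabilities (early, advanced).
#' @slot means,variances 2 x p matrices of per-class Gaussian
#'   class-conditional parameters (rows: class 0, class 1).
#' @rdname TrainedModel-class
#' @aliases NaiveBayesModel
#' @exportClass NaiveBayesModel
setClass("NaiveBayesModel", contains = "TrainedModel",
  representation(priors = "numeric", means = "matrix", variances = "matrix"))

#' @slot W1,b1,W2,b2 layer weights of the single-hidden-layer perceptron.
#' @slot seed RNG seed used for weight initialization.
#' @rdname TrainedModel-class
#' @aliases MLPModel
#' @exportClass MLPModel
setClass("MLPModel", contains = "TrainedModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "numeric",
                 b2 = "numeric", seed = "integer"))

## ---------------------------------------------------------------------------
## Splits and trial summaries

#' SplitPlan: a train-test sampling plan
#'
#' @slot scheme human-readable scheme label.
#' @slot folds list of folds, each a list with integer index vectors
#'   \code{train} and \code{test}.
#' @slot seed RNG seed used to build the plan.
#' @slot stratified whether folds were stratified by class.
#' @aliases SplitPlan
#' @exportClass SplitPlan
setClass("SplitPlan",
  representation(scheme = "character", folds = "list", seed = "integer",
                 stratified = "logical"))

setValidity("SplitPlan", function(object) {
  for (f in object@folds) {
    if (length(intersect(f$train, f$test)))
      return("train and test sets must be disjoint in every fold")
  }
  TRUE
})

#' TrialSummary: AUC stability of one sampling scheme
#'
#' Per-trial AUCs of one (classifier, sampling scheme) pair with their
#' mean, sample SD and the coefficient of variation CV = 100 * SD / mean,
#' rounded half-up to an integer percent. Mean and SD are reported to two
#' decimals; raw values are kept in the slots.
#'
#' @slot scheme scheme label.
#' @slot classifier classifier kind.
#' @slot aucs per-trial AUC values.
#' @slot meanAuc,sdAuc,cvPercent summary statistics (NA where undefined).
#' @aliases TrialSummary
#' @exportClass TrialSummary
setClass("TrialSummary",
  representation(scheme = "character", classifier = "character",
                 aucs = "numeric", meanAuc = "numeric", sdAuc = "numeric",
                 cvPercent = "numeric"))

## ---------------------------------------------------------------------------
## PipelineConfig

#' PipelineConfig: one reproducible end-to-end run
#'
#' @slot sim the \linkS4class{SimulationConfig} for cohort generation.
#' @slot nEarly,nAdvanced,imagesPerSubject cohort layout.
#' @slot levels,distance,directions texture extraction parameters.
#' @slot alpha significance level of the feature screen.
#' @slot classifiers,schemes which models / sampling schemes to run.
#' @slot nTrials repeated trials per percentage split.
#' @slot seed master seed; all stage seeds derive from it.
#' @slot outDir output directory.
#' @slot calibrate run generator calibration before simulating.
#' @slot writeImages write the cohort PNG files.
#' @aliases PipelineConfig
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(sim = "SimulationConfig", nEarly = "integer",
                 nAdvanced = "integer", imagesPerSubject = "integer",
                 levels = "integer", distance = "integer",
                 directions = "numeric", alpha = "numeric",
                 classifiers = "character", schemes = "character",
                 nTrials = "integer", seed = "integer", outDir = "character",
                 calibrate = "logical", writeImages = "logical"))
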