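#' Accessors
#'
#' Accessor generics for the package's S4 containers: \code{pixels} and
#' \code{imageLabel} for \linkS4class{LiverImage}, \code{roiTable} for
#' \linkS4class{ROISet}, \code{glcmProbabilities} / \code{rlmCounts} for
#' the texture matrices, and \code{aucValues} for
#' \linkS4class{TrialSummary}.
#'
#' @param object an object of the matching class.
#' @return The slot contents (a copy).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("imageLabel", function(object) standardGeneric("imageLabel"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("acquisitionId", function(object) standardGeneric("acquisitionId"))

#' @rdname accessors
#' @export
setGeneric("roiTable", function(object) standardGeneric("roiTable"))

#' @rdname accessors
#' @export
setGeneric("glcmProbabilities", function(object)
  standardGeneric("glcmProbabilities"))

#' @rdname accessors
#' @export
setGeneric("rlmCounts", function(object) standardGeneric("rlmCounts"))

#' @rdname accessors
#' @export
setGeneric("aucValues", function(object) standardGeneric("aucValues"))

#' Predict the probability of advanced fibrosis
#'
#' Applies a fitted diagnostic model to new feature data. The model's
#' stored training-fold standardization is applied before evaluation, so
#' rows must be on the original feature scale. Output probabilities refer
#' to class 1 (advanced fibrosis, METAVIR F2--4).
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param newdata a data.frame or matrix with named columns covering
#'   \code{model@featureNames}, or a feature-table
#'   \link[SummarizedExperiment]{SummarizedExperiment}.
#' @return Numeric vector of probabilities in [0, 1].
#' @export
setGeneric("predictProba", function(model, newdata)
  standardGeneric("predictProba"))

## ----- accessor methods ----------------------------------------------------

#' @rdname accessors
setMethod("pixels", "LiverImage", function(object) object@pixels)

#' @rdname accessors
setMethod("imageLabel", "LiverImage", function(object) object@label)

#' @rdname accessors
setMethod("subjectId", "LiverImage", function(object) object@subjectId)

#' @rdname accessors
setMethod("acquisitionId", "LiverImage", function(object) object@acquisitionId)

#' @rdname accessors
setMethod("roiTable", "ROISet", function(object) object@rois)

#' @rdname accessors
setMethod("glcmProbabilities", "GLCMatrix", function(object) object@P)

#' @rdname accessors
setMethod("rlmCounts", "RunLengthMatrix", function(object) object@counts)

#' @rdname accessors
setMethod("aucValues", "TrialSummary", function(object) object@aucs)

## ----- show methods --------------------------------------------------------

setMethod("show", "LiverImage", function(object) {
  cat(sprintf("LiverImage %dx%d  label=%s  subject=%s  acquisition=%s\n",
              nrow(object@pixels), ncol(object@pixels),
              ifelse(is.na(object@label), "unlabeled",
                     as.character(object@label)),
              object@subjectId, object@acquisitionId))
  cat(sprintf("  gray levels: mean %.1f, sd %.1f, range [%d, %d]\n",
              mean(object@pixels), stats::sd(object@pixels),
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet for image '%s': %d ROI(s)\n",
              object@imageRef, nrow(object@rois)))
  print(object@rois)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig %dx%d, psfSigma=%.2f\n",
              object@imageHeight, object@imageWidth, object@psfSigma))
  cat(sprintf("  early:    echo %.1f +/- %.1f, het %.1f +/- %.1f\n",
              object@earlyEchoTarget, object@earlyEchoSd,
              object@earlyHetTarget, object@earlyHetSd))
  cat(sprintf("  advanced: echo %.1f +/- %.1f, het %.1f +/- %.1f\n",
              object@advancedEchoTarget, object@advancedEchoSd,
              object@advancedHetTarget, object@advancedHetSd))
  cat(sprintf("  septae: density %.1f, brightness %.1f, thickness %.1f\n",
              object@septaDensity, object@septaBrightness,
              object@septaThickness))
  cat(sprintf("  gains: %s%s\n", paste(sprintf("%.3f", object@gains),
              collapse = " "),
              if (length(object@achieved)) "  [calibrated]" else ""))
})

setMethod("show", "GLCMatrix", function(object) {
  cat(sprintf("GLCMatrix %dx%d, d=%g, directions {%s}%s\n",
              nrow(object@P), ncol(object@P), object@distance,
              paste(object@directions, collapse = ", "),
              if (object@symmetric) ", symmetric" else ""))
})

setMethod("show", "RunLengthMatrix", function(object) {
  cat(sprintf("RunLengthMatrix %d levels x max run %d: %d runs over %d pixels, directions {%s}\n",
              nrow(object@counts), ncol(object@counts), object@nRuns,
              object@nPixels, paste(object@directions, collapse = ", ")))
})

setMethod("show", "TrainedModel", function(object) {
  cat(sprintf("%s model on %d feature(s): %s\n", object@kind,
              length(object@featureNames),
              paste(object@featureNames, collapse = ", ")))
})

setMethod("show", "SplitPlan", function(object) {
  cat(sprintf("SplitPlan '%s': %d fold(s), seed %d%s\n", object@scheme,
              length(object@folds), object@seed,
              if (object@stratified) ", stratified" else ""))
})

setMethod("show", "TrialSummary", function(object) {
  cat(sprintf("TrialSummary [%s, %s]: %d trial(s)\n", object@scheme,
              object@classifier, length(object@aucs)))
  cat("  AUC:", paste(sprintf("%.2f", object@aucs), collapse = " "), "\n")
  cat(sprintf("  mean %.2f, SD %s, CV %s\n", object@meanAuc,
              ifelse(is.na(object@sdAuc), "NA", sprintf("%.2f", object@sdAuc)),
              ifelse(is.na(object@cvPercent), "NA",
                     sprintf("%d%%", as.integer(object@cvPercent)))))
})
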