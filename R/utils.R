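## Internal helpers shared across modules.

## round-half-up, the convention used for printed CV percentages
.roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## n reproducible sub-seeds derived from one master seed
.subSeeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

## Extract the pixel sub-matrix of a 0-based half-open rectangle
## roi = c(x0, y0, x1, y1); x indexes columns, y indexes rows.
## `image` may be a LiverImage or a plain matrix; roi = NULL means all.
.roiPixels <- function(image, roi = NULL) {
  m <- if (is(image, "LiverImage")) image@pixels else image
  if (is.null(roi)) return(m)
  if (is.data.frame(roi)) roi <- unlist(roi[1, c("x0", "y0", "x1", "y1")])
  roi <- as.integer(roi)
  if (length(roi) != 4L)
    stop("roi must be c(x0, y0, x1, y1), 0-based half-open")
  if (roi[1] < 0L || roi[2] < 0L || roi[3] > ncol(m) || roi[4] > nrow(m) ||
      roi[3] <= roi[1] || roi[4] <= roi[2])
    stop("ROI out of image bounds or empty")
  m[(roi[2] + 1L):roi[4], (roi[1] + 1L):roi[3], drop = FALSE]
}

## iterate over (image, rois) pairs of a cohort list
.cohortCheck <- function(cohort) {
  ok <- is.list(cohort) && length(cohort) > 0 &&
    all(vapply(cohort, function(e)
      is(e$image, "LiverImage") && is(e$rois, "ROISet"), logical(1)))
  if (!ok)
    stop("cohort must be a list of list(image = LiverImage, rois = ROISet)")
  invisible(cohort)
}
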