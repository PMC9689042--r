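## Synthetic B-mode speckle generation.
##
## Model: a complex circular-Gaussian scatterer field is convolved with a
## Gaussian point-spread kernel and the envelope (magnitude) taken. The
## marginal distribution of the envelope is exactly Rayleigh (fully
## developed speckle) with spatial correlation set by the kernel width;
## an affine 8-bit mapping then places the sample mean and SD at the
## requested echo-intensity / heterogeneity targets.

## FFT of a unit-sum Gaussian kernel wrapped on the torus, plus its
## sum of squares (which fixes the Rayleigh scale after convolution).
.gaussKernel <- function(h, w, sigma) {
  yi <- 0:(h - 1); yi <- pmin(yi, h - yi)
  xi <- 0:(w - 1); xi <- pmin(xi, w - xi)
  k <- outer(exp(-yi^2 / (2 * sigma^2)), exp(-xi^2 / (2 * sigma^2)))
  k <- k / sum(k)
  list(fft = stats::fft(k), sumsq = sum(k^2))
}

## circular convolution via FFT (kf = precomputed kernel FFT)
.blurFFT <- function(m, kf) {
  Re(stats::fft(stats::fft(m) * kf, inverse = TRUE)) / length(m)
}

#' Raw correlated Rayleigh speckle field
#'
#' Generates the pre-rescaling envelope of the speckle model: two
#' independent N(0, 1) scatterer fields (real and imaginary parts of a
#' complex circular-Gaussian field) are convolved with a Gaussian kernel
#' of the given sigma and the magnitude taken. The marginal law of the
#' magnitude is Rayleigh with scale \code{sqrt(sum(k^2))} for the
#' unit-sum kernel k; the theoretical scale is returned alongside so the
#' distribution can be checked without estimating parameters.
#'
#' @param height,width field size in pixels.
#' @param psfSigma Gaussian kernel sigma in pixels (>= 0.5).
#' @param seed RNG seed.
#' @return A list with elements \code{magnitude} (height x width matrix)
#'   and \code{scale} (theoretical Rayleigh scale parameter).
#' @export
#' @examples
#' f <- rayleighField(64, 64, 2, seed = 1)
#' mean(f$magnitude) / (f$scale * sqrt(pi / 2))  # ~ 1
rayleighField <- function(height, width, psfSigma, seed) {
  stopifnot(psfSigma >= 0.5, height >= 1, width >= 1)
  k <- .gaussKernel(height, width, psfSigma)
  xy <- withr::with_seed(as.integer(seed), {
    list(x = matrix(stats::rnorm(height * width), height),
         y = matrix(stats::rnorm(height * width), height))
  })
  mag <- sqrt(.blurFFT(xy$x, k$fft)^2 + .blurFFT(xy$y, k$fft)^2)
  list(magnitude = mag, scale = sqrt(k$sumsq))
}

#' Simulate one speckle image with first-order moment targets
#'
#' Draws a correlated Rayleigh envelope (\code{\link{rayleighField}}),
#' then maps it affinely onto 8 bits so that the whole-image sample mean
#' and SD land on \code{echoTarget} / \code{hetTarget}. Because clipping
#' to [0, 255] and integer rounding perturb the moments, the affine map
#' is refined by a short fixed-point iteration (measure clipped moments,
#' re-scale); if the achieved moments still miss the targets by more
#' than 5\% (or half a gray level for very small targets), the target
#' pair is infeasible under 8-bit clipping and a calibration-failure
#' error is raised.
#'
#' @param height,width image size in pixels (>= 64).
#' @param psfSigma speckle correlation length in pixels.
#' @param echoTarget target sample mean gray level, in (0, 255).
#' @param hetTarget target sample SD, in (0, 255).
#' @param seed RNG seed.
#' @param label,subjectId,acquisitionId metadata for the resulting image.
#' @return A \linkS4class{LiverImage}.
#' @export
#' @examples
#' img <- simulateSpeckleField(256, 256, 2, 35.7, 16.9, seed = 1)
#' c(mean(pixels(img)), sd(pixels(img)))
simulateSpeckleField <- function(height, width, psfSigma, echoTarget,
                                 hetTarget, seed, label = NA,
                                 subjectId = NA_character_,
                                 acquisitionId = NA_character_) {
  if (echoTarget <= 0 || echoTarget >= 255 || hetTarget <= 0 ||
      hetTarget >= 255)
    stop("moment targets must lie in (0, 255)")
  f <- rayleighField(height, width, psfSigma, seed)
  m <- f$magnitude
  mu <- mean(m); s <- stats::sd(m)

  a <- hetTarget / s
  b <- echoTarget - a * mu
  for (i in 1:12) {
    x <- pmin(255, pmax(0, a * m + b))
    mx <- mean(x); sx <- stats::sd(x)
    if (sx > 0) a <- a * hetTarget / sx
    b <- b + (echoTarget - mean(pmin(255, pmax(0, a * m + b))))
  }
  px <- pmin(255L, pmax(0L, as.integer(round(a * m + b))))
  dim(px) <- dim(m)

  tolMean <- max(0.05 * echoTarget, 0.5)
  tolSd <- max(0.05 * hetTarget, 0.5)
  if (abs(mean(px) - echoTarget) > tolMean ||
      abs(stats::sd(px) - hetTarget) > tolSd)
    stop(sprintf(paste0(
      "speckle calibration failure: achieved mean %.2f / sd %.2f for ",
      "targets %.2f / %.2f (SD too large for this mean under 8-bit ",
      "clipping?)"), mean(px), stats::sd(px), echoTarget, hetTarget))
  LiverImage(px, label = label, subjectId = subjectId,
             acquisitionId = acquisitionId)
}

#' Overlay collagen-septa-like bright strokes
#'
#' Renders Poisson(\code{density}) random curvilinear bright strokes --
#' random-walk polylines dilated to the given thickness with soft
#' (Gaussian-profile) edges -- and adds them to the image, emulating the
#' hyperechoic collagen septa that make advanced fibrotic parenchyma
#' coarse and heterogeneous. \code{density = 0} returns the input
#' unchanged.
#'
#' @param image a \linkS4class{LiverImage}.
#' @param density expected number of strokes (Poisson mean, >= 0).
#' @param brightness peak additive gray-level offset of a stroke.
#' @param thickness stroke thickness in pixels.
#' @param seed RNG seed.
#' @return A new \linkS4class{LiverImage} with identical metadata.
#' @export
addSeptae <- function(image, density, brightness, thickness = 3, seed = 1) {
  stopifnot(is(image, "LiverImage"), density >= 0)
  if (density == 0) return(image)
  p <- image@pixels
  h <- nrow(p); w <- ncol(p)
  canvas <- withr::with_seed(as.integer(seed), {
    cv <- matrix(0, h, w)
    n <- stats::rpois(1, density)
    if (n > 0) for (i in seq_len(n)) {
      len <- round(stats::runif(1, 0.4, 0.9) * min(h, w))
      ang <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(len, 0, 0.06))
      rr <- round(stats::runif(1, 1, h) + cumsum(sin(ang)))
      cc <- round(stats::runif(1, 1, w) + cumsum(cos(ang)))
      keep <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      cv[cbind(rr[keep], cc[keep])] <- 1
    }
    cv
  })
  if (max(canvas) > 0) {
    k <- .gaussKernel(h, w, max(thickness / 2, 0.5))
    overlay <- .blurFFT(canvas, k$fft)
    overlay <- overlay / max(overlay) * brightness
    p <- pmin(255L, pmax(0L, as.integer(round(p + overlay))))
    dim(p) <- c(h, w)
  }
  LiverImage(p, label = image@label, subjectId = image@subjectId,
             acquisitionId = image@acquisitionId)
}
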