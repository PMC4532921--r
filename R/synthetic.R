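# Synthetic image generator: 1/f^slope Gaussian random fields with
# superimposed oriented step edges and Gabor gratings. Stands in for a
# natural-image database when none is available: it reproduces the two
# statistics the training pipeline cares about -- an approximately
# power-law amplitude spectrum and localized oriented structure.

#' Generate synthetic grayscale images with natural-image statistics
#'
#' Each image is the sum of (i) a Gaussian random field whose amplitude
#' spectrum falls off as 1/f^spectralSlope and (ii) \code{nEdges}
#' oriented elements placed at random positions, alternating between
#' hard step edges and Gabor gratings (random orientation, frequency
#' drawn from 0.05-0.25 cycles/pixel, Gaussian envelope). Pixel units
#' are arbitrary (the preprocessing pipeline z-scores them later).
#' Bit-reproducible given the seed.
#'
#' @param nImages number of images.
#' @param side image side length in pixels (>= 2 x patch side).
#' @param spectralSlope exponent of the 1/f^slope field (0 = white
#'   noise; default 1, the natural-image value).
#' @param nEdges number of oriented elements per image (default 40).
#' @param seed integer seed.
#' @param edgeAmplitude amplitude of the oriented elements relative to
#'   the unit-variance noise field (default 2).
#' @param contrastSigma log-sd of the smooth multiplicative contrast
#'   envelope (default 0.7; 0 disables it). Natural scenes have
#'   log-normally distributed local contrast, which this emulates;
#'   without it every region has the same contrast and a variance
#'   filter retains almost nothing.
#' @return List of \code{nImages} numeric \code{side} x \code{side}
#'   matrices.
#' @export
syntheticImages <- function(nImages, side, spectralSlope = 1,
                            nEdges = 40L, seed = 1L,
                            edgeAmplitude = 2, contrastSigma = 0.7) {
  set.seed(as.integer(seed))
  lapply(seq_len(nImages), function(i)
    syntheticImageOne(side, spectralSlope, nEdges, edgeAmplitude,
                      contrastSigma))
}

syntheticImageOne <- function(side, slope, nEdges, edgeAmplitude,
                              contrastSigma = 0) {
  f <- freqGrid(side, side)
  amp <- ifelse(f > 0, f^(-slope), 0)
  z <- matrix(stats::rnorm(side^2), side, side) +
    1i * matrix(stats::rnorm(side^2), side, side)
  field <- Re(fft(z * amp, inverse = TRUE)) / side
  s <- stats::sd(as.vector(field))
  if (s > 0) field <- field / s

  xy <- expand.grid(x = seq_len(side), y = seq_len(side))
  for (e in seq_len(nEdges)) {
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, 1, side)
    cy <- stats::runif(1, 1, side)
    u <- (xy$x - cx) * cos(theta) + (xy$y - cy) * sin(theta)
    v <- -(xy$x - cx) * sin(theta) + (xy$y - cy) * cos(theta)
    env <- exp(-(u^2 + v^2) / (2 * stats::runif(1, 3, 8)^2))
    if (e %% 2 == 1) {            # step edge through (cx, cy)
      elem <- sign(u) * env
    } else {                      # Gabor grating
      freq <- stats::runif(1, 0.05, 0.25)
      phase <- stats::runif(1, -pi, pi)
      elem <- cos(2 * pi * freq * u + phase) * env
    }
    field <- field + edgeAmplitude * stats::runif(1, 0.5, 1) *
      matrix(elem, side, side)
  }
  if (contrastSigma > 0) {
    # smooth log-normal contrast envelope (steep spectral falloff so
    # it varies over scales much larger than a patch)
    env <- ifelse(f > 0, f^(-2.5), 0)
    ze <- matrix(stats::rnorm(side^2), side, side) +
      1i * matrix(stats::rnorm(side^2), side, side)
    gmod <- Re(fft(ze * env, inverse = TRUE)) / side
    s <- stats::sd(as.vector(gmod))
    if (s > 0) gmod <- gmod / s
    field <- field * exp(contrastSigma * gmod)
  }
  field
}

#' Radially averaged amplitude spectrum of an image
#'
#' Averages |FFT| over annular frequency bins; used to check whitening
#' and the spectral slope of generated images.
#'
#' @param image numeric matrix.
#' @param nBins number of radial bins between 0 and Nyquist.
#' @return data.frame with columns \code{f} (bin-center frequency in
#'   cycles/pixel) and \code{amplitude} (mean |FFT| in the bin).
#' @export
radialSpectrum <- function(image, nBins = 30L) {
  image <- as.matrix(image)
  f <- freqGrid(nrow(image), ncol(image))
  a <- Mod(fft(image))
  sel <- f > 0 & f <= 0.5
  bins <- cut(f[sel], breaks = seq(0, 0.5, length.out = nBins + 1L))
  amp <- tapply(a[sel], bins, mean)
  ctr <- seq(0, 0.5, length.out = nBins + 1L)
  ctr <- (ctr[-1] + ctr[-length(ctr)]) / 2
  out <- data.frame(f = ctr, amplitude = as.numeric(amp))
  out[is.finite(out$amplitude), ]
}
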