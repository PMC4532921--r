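# Image preprocessing: pseudo-whitening, sigmoid rescale, patch
# extraction and variance filtering. Pipeline order is
# whiten -> extract -> sigmoid -> variance-filter.

# Radial frequency grid of an nr x nc image in cycles/pixel.
# Frequencies follow the unshifted DFT layout so the filter can be
# multiplied directly onto fft(image). Nyquist is 0.5 cycles/pixel.
freqGrid <- function(nr, nc) {
  fr <- c(0:floor(nr / 2), -((ceiling(nr / 2) - 1):1)) / nr
  if (nr == 1) fr <- 0
  fc <- c(0:floor(nc / 2), -((ceiling(nc / 2) - 1):1)) / nc
  if (nc == 1) fc <- 0
  sqrt(outer(fr^2, fc^2, "+"))
}

#' Pseudo-whiten a grayscale image
#'
#' Flattens the roughly 1/f amplitude spectrum of natural images by
#' rescaling Fourier coefficients with the radial filter
#' R(f) = f * exp(-(f / f0)^exponent), where f is the modulus of the 2D
#' spatial frequency in cycles/pixel. The filter is real and
#' non-negative, so phases are preserved; the low-pass lobe suppresses
#' the highest (noise-dominated) frequencies. The DC gain is zero, so
#' the output has zero mean.
#'
#' @param image numeric matrix (rows x cols), finite values.
#' @param f0 cutoff frequency in cycles/pixel (> 0). Default 0.2,
#'   i.e. 0.4 x Nyquist.
#' @param exponent exponent of the low-pass envelope (default 4).
#' @return Whitened image, same dimensions, real-valued.
#' @export
whitenImage <- function(image, f0 = 0.2, exponent = 4) {
  image <- as.matrix(image)
  if (!all(is.finite(image)))
    stop("whitenImage: image must contain only finite values")
  if (f0 <= 0) stop("whitenImage: f0 must be > 0")
  f <- freqGrid(nrow(image), ncol(image))
  R <- f * exp(-(f / f0)^exponent)
  out <- fft(fft(image) * R, inverse = TRUE) / length(image)
  re <- Re(out)
  im <- max(abs(Im(out)))
  if (im > 1e-10 * max(abs(re), 1))
    warning("whitenImage: non-negligible imaginary residue discarded")
  re
}

#' Sigmoid rescale of pixel intensities into (0, 1)
#'
#' Applies the logistic function to z-scored intensities:
#' logistic(gain * (x - mean(x)) / sd(x)). Monotone in the input; a
#' pixel at the mean maps to 0.5. A zero-variance input maps entirely
#' to 0.5. For a \linkS4class{PatchSet} the mean and standard deviation
#' are taken over all patch pixels jointly, so relative contrast between
#' patches is preserved.
#'
#' @param x numeric matrix (an image) or a \linkS4class{PatchSet}.
#' @param gain slope of the logistic in z-score units (default 1).
#' @return Object of the same type with values in (0, 1).
#' @export
sigmoidRescale <- function(x, gain = 1) {
  if (is(x, "PatchSet")) {
    m <- x@patches
    out <- sigmoidRescaleMatrix(m, gain)
    pre <- x@preprocessing
    pre$sigmoid_gain <- gain
    return(new("PatchSet", patches = out, patchSide = x@patchSide,
               provenance = x@provenance, preprocessing = pre))
  }
  sigmoidRescaleMatrix(as.matrix(x), gain)
}

sigmoidRescaleMatrix <- function(m, gain) {
  if (!all(is.finite(m)))
    stop("sigmoidRescale: input must be finite")
  s <- stats::sd(as.vector(m))
  if (!is.finite(s) || s == 0)
    return(matrix(0.5, nrow(m), ncol(m)))
  stats::plogis(gain * (m - mean(m)) / s)
}

#' Extract random square patches from a list of images
#'
#' Draws \code{nPatches} uniformly random top-left offsets (0-based,
#' half-open windows) across the supplied images and vectorizes each
#' patch column-major into a row of the patch matrix. Reproducible
#' given the seed; provenance (image, row, col) is recorded per patch.
#'
#' @param images a list of numeric matrices, or a single matrix.
#' @param nPatches number of patches to draw (>= 1).
#' @param side patch side length in pixels (default 14).
#' @param seed integer seed.
#' @return A \linkS4class{PatchSet}.
#' @export
extractPatches <- function(images, nPatches, side = 14L, seed = 1L) {
  if (is.matrix(images)) images <- list(images)
  side <- as.integer(side)
  nPatches <- as.integer(nPatches)
  if (nPatches < 1L) stop("extractPatches: nPatches must be >= 1")
  dims <- vapply(images, dim, integer(2))
  if (any(dims < side))
    stop("extractPatches: patch larger than some image dimension")
  set.seed(as.integer(seed))
  img <- sample.int(length(images), nPatches, replace = TRUE)
  maxr <- dims[1, img] - side  # max 0-based row offset
  maxc <- dims[2, img] - side
  r0 <- floor(stats::runif(nPatches) * (maxr + 1))
  c0 <- floor(stats::runif(nPatches) * (maxc + 1))
  P <- matrix(0, nPatches, side^2)
  for (l in seq_len(nPatches)) {
    blk <- images[[img[l]]][(r0[l] + 1):(r0[l] + side),
                            (c0[l] + 1):(c0[l] + side)]
    P[l, ] <- as.vector(blk)
  }
  patchSet(P, patchSide = side,
           provenance = data.frame(image = img, row = as.integer(r0),
                                   col = as.integer(c0)),
           preprocessing = list(extract_seed = as.integer(seed)))
}

#' Filter out low-variance patches
#'
#' Retains exactly the patches whose per-patch pixel variance
#' (population convention, 1/N) is greater than or equal to the
#' threshold; patches with variance strictly below it are dropped.
#' Row order is preserved. Intended to run on post-sigmoid values.
#'
#' @param x a \linkS4class{PatchSet}.
#' @param threshold non-negative variance threshold (default 0.1).
#' @return The filtered \linkS4class{PatchSet}.
#' @export
filterLowVariance <- function(x, threshold = 0.1) {
  if (threshold < 0) stop("filterLowVariance: threshold must be >= 0")
  v <- patchVariances(x)
  keep <- v >= threshold
  if (!any(keep))
    warning("filterLowVariance: no patches retained")
  out <- x[keep]
  out@preprocessing$variance_threshold <- threshold
  out
}

#' Per-patch pixel variances (population convention)
#' @param x a \linkS4class{PatchSet}.
#' @return Numeric vector of length \code{nPatches(x)}.
#' @export
patchVariances <- function(x) {
  m <- x@patches
  rowMeans(m^2) - rowMeans(m)^2
}
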