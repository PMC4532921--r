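# Deterministic patchwise image reconstruction through a trained RBM.

#' Reconstruct a preprocessed image through an RBM
#'
#' Tiles the image into non-overlapping patchSide x patchSide blocks;
#' for each block v the hidden activation probabilities p(h | v) are
#' computed and the block is recovered as p(v | p(h | v)), using
#' probabilities end to end (no sampling), so the reconstruction is
#' fully deterministic. Margins left when the image dimensions are not
#' multiples of the patch side are cropped from both images before the
#' error is computed.
#'
#' @param model an \linkS4class{RBMModel} trained on
#'   patchSide^2-dimensional patches.
#' @param image numeric matrix already preprocessed (whitened +
#'   sigmoid-rescaled) to [0, 1].
#' @param patchSide patch side length; defaults to sqrt(Nv) of the
#'   model.
#' @return List with \code{original} and \code{reconstructed} (cropped
#'   to the covered area), \code{mse}, \code{psnr} (dB), and
#'   \code{perPatchMse}, a (rows/side) x (cols/side) matrix of
#'   per-block mean squared errors.
#' @export
reconstructImage <- function(model, image, patchSide = NULL) {
  image <- as.matrix(image)
  if (is.null(patchSide))
    patchSide <- as.integer(round(sqrt(nVisible(model))))
  if (patchSide^2 != nVisible(model))
    stop("reconstructImage: patchSide^2 must equal Nv")
  nbr <- nrow(image) %/% patchSide
  nbc <- ncol(image) %/% patchSide
  if (nbr < 1L || nbc < 1L)
    stop("reconstructImage: image smaller than one patch")
  rows <- nbr * patchSide; cols <- nbc * patchSide
  orig <- image[seq_len(rows), seq_len(cols), drop = FALSE]

  # vectorize all blocks into an (nbr*nbc) x Nv matrix
  blocks <- matrix(0, nbr * nbc, patchSide^2)
  bi <- 1L
  for (bc in seq_len(nbc)) {
    for (br in seq_len(nbr)) {
      blk <- orig[((br - 1) * patchSide + 1):(br * patchSide),
                  ((bc - 1) * patchSide + 1):(bc * patchSide)]
      blocks[bi, ] <- as.vector(blk)
      bi <- bi + 1L
    }
  }
  Ph <- probHiddenGivenVisible(model, blocks)
  Vh <- probVisibleGivenHidden(model, Ph)

  recon <- matrix(0, rows, cols)
  perPatch <- matrix(0, nbr, nbc)
  bi <- 1L
  for (bc in seq_len(nbc)) {
    for (br in seq_len(nbr)) {
      hat <- matrix(Vh[bi, ], patchSide, patchSide)
      recon[((br - 1) * patchSide + 1):(br * patchSide),
            ((bc - 1) * patchSide + 1):(bc * patchSide)] <- hat
      perPatch[br, bc] <- mean((blocks[bi, ] - Vh[bi, ])^2)
      bi <- bi + 1L
    }
  }
  mse <- mean(perPatch)
  list(original = orig, reconstructed = recon, mse = mse,
       psnr = 10 * log10(1 / mse), perPatchMse = perPatch)
}

#' Split images into training and held-out test sets
#'
#' Seeded random split into disjoint train/test subsets, as used for
#' the reconstruction experiment (e.g. 8 training and 2 test images).
#'
#' @param images list of images (or any list).
#' @param nTest number of test elements (< length(images)).
#' @param seed integer seed.
#' @return List with elements \code{train} and \code{test}.
#' @export
holdoutSplit <- function(images, nTest, seed = 1L) {
  n <- length(images)
  if (nTest >= n) stop("holdoutSplit: nTest must be < number of images")
  set.seed(as.integer(seed))
  testIdx <- if (nTest > 0) sample.int(n, nTest) else integer(0)
  list(train = images[setdiff(seq_len(n), testIdx)],
       test = images[testIdx])
}
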