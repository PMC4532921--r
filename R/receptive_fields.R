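# Reverse-correlation receptive-field estimation and comparison with
# basis images (columns of W).

#' Estimate a receptive field by reverse correlation
#'
#' RF = sum_s p(h_j = 1 | v_s) v_s over a stimulus ensemble: the
#' activation-probability-weighted sum of stimulus patches. With
#' \code{centered = TRUE} (the default for Gabor fitting) the ensemble
#' DC pedestal S * mean(p) * mean-patch is subtracted, which equals
#' replacing p and v by their deviations from the ensemble means.
#'
#' @param model an \linkS4class{RBMModel}.
#' @param stimuli \linkS4class{PatchSet} or L x Nv matrix of stimuli.
#' @param unit hidden unit index (1-based).
#' @param centered subtract the mean-activation x mean-stimulus
#'   pedestal (default FALSE: the raw reverse-correlation sum).
#' @param cap maximum number of stimuli used (default 10000, seeded
#'   subsample).
#' @param seed seed for the subsample.
#' @return patchSide x patchSide numeric matrix (or sqrt(Nv) side for
#'   plain matrices).
#' @export
estimateRF <- function(model, stimuli, unit, centered = FALSE,
                       cap = 10000L, seed = 1L) {
  side <- if (is(stimuli, "PatchSet")) patchSide(stimuli)
          else as.integer(round(sqrt(ncol(asPatchMatrix(stimuli)))))
  V <- asPatchMatrix(stimuli)
  if (nrow(V) < 1L) stop("estimateRF: empty stimulus set")
  if (nrow(V) > cap) {
    set.seed(as.integer(seed))
    V <- V[sample.int(nrow(V), cap), , drop = FALSE]
  }
  p <- probHiddenGivenVisible(model, V)[, unit]
  rf <- as.numeric(crossprod(V, p))
  if (centered)
    rf <- rf - nrow(V) * mean(p) * colMeans(V)
  matrix(rf, side, side)
}

#' Receptive fields of all hidden units
#'
#' @inheritParams estimateRF
#' @return Nv x Nh matrix; column j is the vectorized RF of unit j.
#' @export
estimateRFs <- function(model, stimuli, centered = FALSE,
                        cap = 10000L, seed = 1L) {
  V <- asPatchMatrix(stimuli)
  if (nrow(V) > cap) {
    set.seed(as.integer(seed))
    V <- V[sample.int(nrow(V), cap), , drop = FALSE]
  }
  P <- probHiddenGivenVisible(model, V)     # L x Nh
  RF <- crossprod(V, P)                     # Nv x Nh
  if (centered)
    RF <- RF - nrow(V) * outer(colMeans(V), colMeans(P))
  RF
}

#' Agreement between a receptive field and a basis image
#'
#' Pearson correlation of the best linear fit RF ~ alpha * basis +
#' beta; 1 when the RF equals the basis column up to a positive affine
#' map, -1 for a sign flip.
#'
#' @param rf receptive field (matrix or vector).
#' @param basis basis image (column of W), same length.
#' @return Correlation coefficient in [-1, 1]; 0 with a warning when
#'   either input has zero variance.
#' @export
rfBasisAgreement <- function(rf, basis) {
  x <- as.numeric(rf); y <- as.numeric(basis)
  if (length(x) != length(y))
    stop("rfBasisAgreement: size mismatch")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("rfBasisAgreement: zero-variance input")
    return(0)
  }
  stats::cor(x, y)
}
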