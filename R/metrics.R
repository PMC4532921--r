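# Treves-Rolls selectivity (lifetime sparseness), population sparsity,
# and dead-neuron counting, computed on activation probabilities.

#' Activation probability matrix for a stimulus set
#'
#' R[l, j] = p(h_j = 1 | v_l) for every stimulus l and hidden unit j.
#'
#' @param model an \linkS4class{RBMModel}.
#' @param patches \linkS4class{PatchSet} or L x Nv matrix.
#' @return L x Nh matrix of probabilities.
#' @export
activationMatrix <- function(model, patches) {
  V <- asPatchMatrix(patches)
  probHiddenGivenVisible(model, V)
}

# Treves-Rolls statistic 1 - (mean r)^2 / (mean r^2); 0/0 (all-zero
# responses) is defined as 0 -- such a unit is maximally non-selective
# and is flagged by the dead-neuron count instead.
trevesRolls <- function(r) {
  ms <- mean(r^2)
  if (ms == 0) return(0)
  1 - mean(r)^2 / ms
}

#' Treves-Rolls selectivity of one neuron across stimuli
#'
#' 1 - (sum(r)/L)^2 / (sum(r^2)/L) over the L stimulus responses r;
#' 0 for a constant response profile and 1 - 1/L for a one-hot
#' profile. Scale-invariant. An all-zero profile is defined as 0.
#'
#' @param responses numeric vector of activation probabilities in
#'   [0, 1], length >= 2.
#' @return Scalar in [0, 1 - 1/L].
#' @export
selectivity <- function(responses) {
  if (length(responses) < 2L)
    stop("selectivity: need at least 2 responses")
  trevesRolls(responses)
}

#' Treves-Rolls population sparsity of one stimulus across neurons
#'
#' Same functional form as \code{\link{selectivity}}, evaluated across
#' the Nh neuron responses to a single stimulus.
#'
#' @param responses numeric vector of activation probabilities in
#'   [0, 1], length >= 2.
#' @return Scalar in [0, 1 - 1/Nh].
#' @export
sparsity <- function(responses) {
  if (length(responses) < 2L)
    stop("sparsity: need at least 2 responses")
  trevesRolls(responses)
}

#' Mean selectivity over all neurons
#'
#' Column-wise Treves-Rolls selectivity of the activation matrix,
#' averaged over neurons.
#'
#' @param R L x Nh activation matrix (stimuli x neurons).
#' @return Scalar mean selectivity.
#' @export
meanSelectivity <- function(R) {
  R <- as.matrix(R)
  mean(apply(R, 2, trevesRolls))
}

#' Mean population sparsity over all stimuli
#'
#' Row-wise Treves-Rolls sparsity of the activation matrix, averaged
#' over stimuli.
#'
#' @param R L x Nh activation matrix (stimuli x neurons).
#' @return Scalar mean sparsity.
#' @export
meanSparsity <- function(R) {
  R <- as.matrix(R)
  mean(apply(R, 1, trevesRolls))
}

#' Count dead neurons
#'
#' A unit is dead when its maximal activation probability over all
#' stimuli is strictly below the threshold (default 0.1).
#'
#' @param R L x Nh activation matrix.
#' @param threshold activation threshold in (0, 1).
#' @return Integer count of dead units.
#' @export
countDeadNeurons <- function(R, threshold = 0.1) {
  if (threshold <= 0 || threshold >= 1)
    stop("countDeadNeurons: threshold must be in (0, 1)")
  R <- as.matrix(R)
  sum(apply(R, 2, max) < threshold)
}

#' Summary metrics of a trained model on a stimulus set
#'
#' Convenience wrapper: activation matrix (optionally subsampled to
#' \code{cap} stimuli, seeded), mean selectivity, mean sparsity and
#' dead-neuron count in one call.
#'
#' @param model an \linkS4class{RBMModel}.
#' @param patches \linkS4class{PatchSet} or matrix of stimuli.
#' @param cap maximum number of stimuli used (default 5000; Inf for
#'   all).
#' @param deadThreshold dead-neuron activation threshold.
#' @param seed seed for the subsample.
#' @return data.frame with columns \code{meanSelectivity},
#'   \code{meanSparsity}, \code{deadNeurons}, \code{nStimuli}.
#' @export
modelMetrics <- function(model, patches, cap = 5000L,
                         deadThreshold = 0.1, seed = 1L) {
  V <- asPatchMatrix(patches)
  if (nrow(V) > cap) {
    set.seed(as.integer(seed))
    V <- V[sample.int(nrow(V), cap), , drop = FALSE]
  }
  R <- activationMatrix(model, V)
  data.frame(meanSelectivity = meanSelectivity(R),
             meanSparsity = meanSparsity(R),
             deadNeurons = countDeadNeurons(R, deadThreshold),
             nStimuli = nrow(V))
}
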