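# Binary-unit restricted Boltzmann machine: energy, conditionals,
# exact small-instance oracles (log-likelihood, gradient) and the CD-k
# gradient estimator.
#
# Visible data are accepted as reals in [0, 1] and treated as
# activation probabilities wherever a binary v is expected: positive
# statistics and the final negative-phase statistics are written in
# probabilities; intermediate Gibbs states sample binary h (and binary
# v between alternations when k > 1).

logistic <- function(x) stats::plogis(x)

asPatchMatrix <- function(data) {
  if (is(data, "PatchSet")) return(data@patches)
  if (is.null(dim(data))) return(matrix(data, nrow = 1))
  as.matrix(data)
}

#' Energy of a joint (v, h) configuration
#'
#' E(v, h) = -t(v) W h - t(h) b - t(v) c.
#'
#' @param model an \linkS4class{RBMModel}.
#' @param v length-Nv visible vector.
#' @param h length-Nh hidden vector.
#' @return Scalar energy.
#' @export
rbmEnergy <- function(model, v, h) {
  if (length(v) != nVisible(model) || length(h) != nHidden(model))
    stop("rbmEnergy: v/h dimensions do not match the model")
  -as.numeric(t(v) %*% model@W %*% h) - sum(h * model@b) -
    sum(v * model@c)
}

#' Hidden activation probabilities p(h_j = 1 | v)
#'
#' Hidden units are conditionally independent given v:
#' p(h_j = 1 | v) = logistic(t(v) W[, j] + b[j]).
#'
#' @param model an \linkS4class{RBMModel}.
#' @param v a length-Nv vector, an L x Nv matrix (one row per
#'   stimulus), or a \linkS4class{PatchSet}.
#' @return Length-Nh vector, or L x Nh matrix for matrix input.
#' @export
probHiddenGivenVisible <- function(model, v) {
  single <- is.null(dim(v)) && !is(v, "PatchSet")
  V <- asPatchMatrix(v)
  if (ncol(V) != nVisible(model))
    stop("probHiddenGivenVisible: dimension mismatch")
  P <- logistic(sweep(V %*% model@W, 2, model@b, "+"))
  if (single) as.numeric(P) else P
}

#' Visible activation probabilities p(v_i = 1 | h)
#'
#' p(v_i = 1 | h) = logistic(W[i, ] h + c[i]).
#'
#' @param model an \linkS4class{RBMModel}.
#' @param h a length-Nh vector or an L x Nh matrix.
#' @return Length-Nv vector, or L x Nv matrix for matrix input.
#' @export
probVisibleGivenHidden <- function(model, h) {
  single <- is.null(dim(h))
  H <- if (single) matrix(h, nrow = 1) else as.matrix(h)
  if (ncol(H) != nHidden(model))
    stop("probVisibleGivenHidden: dimension mismatch")
  P <- logistic(sweep(H %*% t(model@W), 2, model@c, "+"))
  if (single) as.numeric(P) else P
}

# Guard for exact oracles: refuse enumerations above 2^20 states.
enumGuard <- function(model) {
  nEnum <- min(nVisible(model), nHidden(model))
  if (nEnum > 20L)
    stop("exact computation refused: min(Nv, Nh) = ", nEnum,
         " exceeds the 2^20 enumeration guard")
  nEnum
}

# All binary configurations of n units as a 2^n x n matrix.
binaryStates <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  dimnames(g) <- NULL
  g
}

# log(sum(exp(x))) stable
logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Log partition function by enumerating the smaller layer and
# marginalizing the other analytically:
#   Z = sum_h exp(t(b) h) prod_i (1 + exp(W[i,] h + c_i))   (h smaller)
#   Z = sum_v exp(t(c) v) prod_j (1 + exp(t(v) W[,j] + b_j)) (v smaller)
logPartition <- function(model) {
  enumGuard(model)
  W <- model@W; b <- model@b; cc <- model@c
  if (nHidden(model) <= nVisible(model)) {
    H <- binaryStates(nHidden(model))
    act <- sweep(H %*% t(W), 2, cc, "+")          # 2^Nh x Nv
    logSumExp(H %*% b + rowSums(log1p(exp(act))))
  } else {
    V <- binaryStates(nVisible(model))
    act <- sweep(V %*% W, 2, b, "+")              # 2^Nv x Nh
    logSumExp(V %*% cc + rowSums(log1p(exp(act))))
  }
}

# Free energy F(v) = -t(c) v - sum_j log(1 + exp(t(v) W[,j] + b_j));
# log p(v) = -F(v) - log Z. Accepts an L x Nv matrix.
freeEnergy <- function(model, V) {
  act <- sweep(V %*% model@W, 2, model@b, "+")
  -(V %*% model@c) - rowSums(log1p(exp(act)))
}

#' Exact average log-likelihood of visible data (small models only)
#'
#' Computes mean log p(v) over the data rows via the analytic free
#' energy and a partition function obtained by enumerating all binary
#' states of the smaller layer. Refuses models whose smaller layer
#' exceeds 20 units.
#'
#' @param model an \linkS4class{RBMModel}.
#' @param data a \linkS4class{PatchSet}, matrix (rows = examples) or
#'   single vector of visibles in [0, 1].
#' @return Scalar mean log-likelihood.
#' @export
exactLogLikelihood <- function(model, data) {
  V <- asPatchMatrix(data)
  lZ <- logPartition(model)
  mean(-freeEnergy(model, V)) - lZ
}

#' Exact log-likelihood gradient (small models only)
#'
#' Data-term expectation minus model-term expectation, the latter
#' computed by exact enumeration of the smaller layer. Serves as the
#' oracle against which the CD-k estimator is validated.
#'
#' @param model an \linkS4class{RBMModel}.
#' @param data visibles as in \code{\link{exactLogLikelihood}}.
#' @return List with elements \code{dW} (Nv x Nh), \code{db} (Nh),
#'   \code{dc} (Nv): the ascent direction on the mean log-likelihood.
#' @export
exactGradient <- function(model, data) {
  enumGuard(model)
  V <- asPatchMatrix(data)
  L <- nrow(V)
  Ph <- probHiddenGivenVisible(model, V)          # L x Nh
  dataW <- crossprod(V, Ph) / L
  datab <- colMeans(Ph)
  datac <- colMeans(V)

  W <- model@W; b <- model@b; cc <- model@c
  if (nHidden(model) <= nVisible(model)) {
    H <- binaryStates(nHidden(model))             # S x Nh
    act <- sweep(H %*% t(W), 2, cc, "+")          # S x Nv
    lw <- as.numeric(H %*% b) + rowSums(log1p(exp(act)))
    p <- exp(lw - logSumExp(lw))                  # p(h)
    Ev_h <- logistic(act)                         # E[v | h]
    modelW <- crossprod(Ev_h * p, H)              # Nv x Nh
    modelb <- colSums(H * p)
    modelc <- colSums(Ev_h * p)
  } else {
    Vs <- binaryStates(nVisible(model))           # S x Nv
    act <- sweep(Vs %*% W, 2, b, "+")             # S x Nh
    lw <- as.numeric(Vs %*% cc) + rowSums(log1p(exp(act)))
    p <- exp(lw - logSumExp(lw))                  # p(v)
    Eh_v <- logistic(act)                         # E[h | v]
    modelW <- crossprod(Vs * p, Eh_v)
    modelb <- colSums(Eh_v * p)
    modelc <- colSums(Vs * p)
  }
  list(dW = dataW - modelW, db = datab - modelb, dc = datac - modelc)
}

#' CD-k stochastic gradient estimate
#'
#' Positive phase uses the data rows v and p(h | v). The negative phase
#' runs k alternations of (sample binary h, reconstruct v); the final
#' statistics are taken in probabilities: v- is the reconstructed
#' visible probability vector and the hidden statistics use p(h | v-).
#' Intermediate visible states (k > 1) are sampled binary. Uses R's
#' RNG stream, so results are reproducible under \code{set.seed}.
#'
#' @param model an \linkS4class{RBMModel}.
#' @param batch visibles (PatchSet, matrix, or vector), values in
#'   [0, 1]; must be nonempty.
#' @param k number of Gibbs alternations (>= 1).
#' @return List with \code{dW}, \code{db}, \code{dc} (ascent direction)
#'   plus \code{vNeg} (the final reconstruction probabilities, used for
#'   the training-history cross-entropy).
#' @export
cdGradient <- function(model, batch, k = 1L) {
  V <- asPatchMatrix(batch)
  L <- nrow(V)
  if (L < 1L) stop("cdGradient: empty batch")
  if (k < 1L) stop("cdGradient: k must be >= 1")
  PhPos <- probHiddenGivenVisible(model, V)
  vCur <- V
  for (t in seq_len(k)) {
    Ph <- if (t == 1L) PhPos else probHiddenGivenVisible(model, vCur)
    Hs <- matrix(stats::rbinom(length(Ph), 1L, Ph), nrow(Ph), ncol(Ph))
    Pv <- probVisibleGivenHidden(model, Hs)
    vCur <- if (t < k)
      matrix(stats::rbinom(length(Pv), 1L, Pv), nrow(Pv), ncol(Pv))
    else Pv
  }
  PhNeg <- probHiddenGivenVisible(model, vCur)
  list(dW = (crossprod(V, PhPos) - crossprod(vCur, PhNeg)) / L,
       db = colMeans(PhPos) - colMeans(PhNeg),
       dc = colMeans(V) - colMeans(vCur),
       vNeg = vCur)
}
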