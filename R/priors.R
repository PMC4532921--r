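# Diversity prior over the RBM weight matrix, plus the sparse-group
# and selectivity comparison regularizers.
#
# Sign convention: every *Gradient function returns the contribution to
# the gradient-ASCENT update of the MAP objective, i.e. the gradient of
# minus the (weighted) penalty. Training simply adds it to the CD
# log-likelihood gradient.

EPS_NORM <- 1e-12  # floor on column norms to avoid division by zero

colNorms <- function(W) pmax(sqrt(colSums(W^2)), EPS_NORM)

#' Pairwise squared-cosine similarity penalty of weight columns
#'
#' Sum over all ordered pairs (j, k), j != k, of the squared cosine
#' similarity between columns j and k of W: each unordered pair is
#' counted twice. Zero for mutually orthogonal columns; equals
#' Nh (Nh - 1) when all columns are parallel. Invariant to column
#' permutation, sign flips and per-column rescaling.
#'
#' @param W Nv x Nh numeric matrix.
#' @param epsGuard if TRUE (default) zero-norm columns are floored at
#'   1e-12; if FALSE a zero column is an error.
#' @return Scalar penalty in [0, Nh (Nh - 1)].
#' @export
squaredCosinePenalty <- function(W, epsGuard = TRUE) {
  W <- as.matrix(W)
  n <- sqrt(colSums(W^2))
  if (!epsGuard && any(n == 0))
    stop("squaredCosinePenalty: zero-norm column")
  Wn <- sweep(W, 2, pmax(n, EPS_NORM), "/")
  Cn <- crossprod(Wn)
  sum(Cn^2) - sum(diag(Cn)^2)
}

#' Unnormalized log-density of the diversity prior
#'
#' log p(W) = -lambda * squaredCosinePenalty(W), up to the (constant)
#' log normalizer. Monotone decreasing in the penalty.
#'
#' @param W Nv x Nh numeric matrix.
#' @param lambdaDiv prior weight lambda (>= 0).
#' @return Scalar, <= 0.
#' @export
priorLogDensity <- function(W, lambdaDiv) {
  -lambdaDiv * squaredCosinePenalty(W)
}

#' Gradient contribution of the diversity prior
#'
#' Exact ascent gradient of the log prior under the unit-norm
#' treatment of the constraint: the similarity term is the gradient of
#' -lambda * sum over ordered pairs (t(W[,j]) W[,k])^2, i.e. column j
#' receives -4 lambda * sum_{k != j} (t(W[,j]) W[,k]) W[,k]; the soft
#' norm term is the gradient of -lambda C sum_j (||W[,j]|| - 1)^2 and
#' vanishes on unit-norm columns (and is irrelevant under hard
#' renormalization).
#'
#' @param W Nv x Nh numeric matrix.
#' @param lambdaDiv prior weight lambda (>= 0).
#' @param C soft norm-penalty constant (>= 0, default 1).
#' @return List with \code{dW} (Nv x Nh ascent contribution) and
#'   \code{penalty} (the current squared-cosine penalty value).
#' @export
diversityGradient <- function(W, lambdaDiv, C = 1) {
  W <- as.matrix(W)
  if (lambdaDiv < 0 || C < 0)
    stop("diversityGradient: lambdaDiv and C must be >= 0")
  pen <- squaredCosinePenalty(W)
  if (lambdaDiv == 0)
    return(list(dW = matrix(0, nrow(W), ncol(W)), penalty = pen))
  G <- crossprod(W)                       # t(W) W, Nh x Nh
  diag(G) <- 0                            # exclude k = j
  dSim <- -4 * lambdaDiv * (W %*% G)
  nrm <- colNorms(W)
  dNorm <- -2 * lambdaDiv * C *
    sweep(W, 2, (nrm - 1) / nrm, "*")
  list(dW = dSim + dNorm, penalty = pen)
}

#' Gradient contribution of the sparse-group (l1/l2) regularizer
#'
#' Reconstruction of the activation regularizer of sparse-group RBMs:
#' the penalty is weight * mean over stimuli of ||p||_1 / ||p||_2 with
#' p = p(h | v). Returns the ascent contribution (minus the penalty
#' gradient) with respect to W and b, chained through the logistic.
#'
#' @param W Nv x Nh weight matrix.
#' @param b length-Nh hidden bias.
#' @param batch L x Nv matrix or \linkS4class{PatchSet} of stimuli.
#' @param weight regularizer weight (>= 0, default 0.1).
#' @return List with \code{dW}, \code{db} (ascent contributions) and
#'   \code{penalty}.
#' @export
sparseGroupGradient <- function(W, b, batch, weight = 0.1) {
  V <- asPatchMatrix(batch)
  L <- nrow(V)
  if (L < 1L) stop("sparseGroupGradient: empty batch")
  P <- logistic(sweep(V %*% W, 2, b, "+"))        # L x Nh
  l1 <- rowSums(P)
  l2 <- pmax(sqrt(rowSums(P^2)), EPS_NORM)
  pen <- weight * mean(l1 / l2)
  if (weight == 0)
    return(list(dW = matrix(0, nrow(W), ncol(W)),
                db = numeric(length(b)), penalty = pen))
  # d(l1/l2)/dP[l,j] = 1/l2[l] - l1[l] P[l,j] / l2[l]^3
  dP <- 1 / l2 - (l1 / l2^3) * P
  D <- dP * P * (1 - P) * (weight / L)            # d penalty / d z
  list(dW = -crossprod(V, D), db = -colSums(D), penalty = pen)
}

#' Gradient contribution of the selectivity regularizer
#'
#' Reconstruction of the mean-activation regularizer of selective
#' RBMs: the penalty is weight * sum_j (mean_l p(h_j = 1 | v_l) -
#' target)^2, pushing each unit's average activation toward a small
#' target. Returns the ascent contribution with respect to W and b.
#'
#' @param W Nv x Nh weight matrix.
#' @param b length-Nh hidden bias.
#' @param batch L x Nv matrix or \linkS4class{PatchSet} of stimuli.
#' @param weight regularizer weight (>= 0, default 0.1).
#' @param targetActivation target mean activation in (0, 1), default
#'   0.02.
#' @return List with \code{dW}, \code{db} and \code{penalty}.
#' @export
selectiveGradient <- function(W, b, batch, weight = 0.1,
                              targetActivation = 0.02) {
  if (targetActivation <= 0 || targetActivation >= 1)
    stop("selectiveGradient: targetActivation must be in (0, 1)")
  V <- asPatchMatrix(batch)
  L <- nrow(V)
  P <- logistic(sweep(V %*% W, 2, b, "+"))
  m <- colMeans(P)
  pen <- weight * sum((m - targetActivation)^2)
  if (weight == 0)
    return(list(dW = matrix(0, nrow(W), ncol(W)),
                db = numeric(length(b)), penalty = pen))
  D <- sweep(P * (1 - P), 2,
             2 * weight * (m - targetActivation) / L, "*")
  list(dW = -crossprod(V, D), db = -colSums(D), penalty = pen)
}
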