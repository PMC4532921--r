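#' @import methods
NULL

#' PatchSet: a set of vectorized image patches
#'
#' Container for an L x Nv matrix of image patches, one patch per row,
#' each the column-major vectorization of a square \code{patchSide} x
#' \code{patchSide} window. Provenance records where each patch was cut
#' from (image index and 0-based top-left offset). After full
#' preprocessing (whitening, sigmoid rescale) all values lie in [0, 1];
#' intermediate (pre-sigmoid) sets may hold arbitrary finite reals.
#'
#' @slot patches numeric matrix, L x Nv with Nv = patchSide^2.
#' @slot patchSide integer, side length of the square patch in pixels.
#' @slot provenance data.frame with columns \code{image}, \code{row},
#'   \code{col} (0-based top-left offsets), one row per patch.
#' @slot preprocessing list of preprocessing parameters applied so far
#'   (free-form; recorded for reproducibility).
#'
#' @aliases PatchSet-class
#' @exportClass PatchSet
setClass("PatchSet",
  representation(
    patches = "matrix",
    patchSide = "integer",
    provenance = "data.frame",
    preprocessing = "list"
  ),
  prototype(
    patches = matrix(numeric(0), 0, 0),
    patchSide = 0L,
    provenance = data.frame(image = integer(0), row = integer(0),
                            col = integer(0)),
    preprocessing = list()
  )
)

setValidity("PatchSet", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@patches)))
    msg <- c(msg, "patches must be finite")
  if (length(object@patchSide) != 1L || object@patchSide < 1L)
    msg <- c(msg, "patchSide must be a positive scalar integer")
  if (ncol(object@patches) != object@patchSide^2)
    msg <- c(msg, "ncol(patches) must equal patchSide^2")
  if (nrow(object@provenance) != nrow(object@patches))
    msg <- c(msg, "provenance must have one row per patch")
  if (length(msg)) msg else TRUE
})

#' Construct a PatchSet
#'
#' @param patches L x Nv numeric matrix of row-vectorized patches.
#' @param patchSide side length in pixels; defaults to sqrt(Nv).
#' @param provenance optional data.frame (image, row, col) per patch.
#' @param preprocessing optional list of preprocessing parameters.
#' @return A \linkS4class{PatchSet}.
#' @export
patchSet <- function(patches, patchSide = NULL, provenance = NULL,
                     preprocessing = list()) {
  patches <- as.matrix(patches)
  if (is.null(patchSide)) {
    patchSide <- as.integer(round(sqrt(ncol(patches))))
  }
  patchSide <- as.integer(patchSide)
  if (is.null(provenance)) {
    provenance <- data.frame(image = rep(NA_integer_, nrow(patches)),
                             row = NA_integer_, col = NA_integer_)
  }
  new("PatchSet", patches = patches, patchSide = patchSide,
      provenance = provenance, preprocessing = preprocessing)
}

#' Number of patches in a PatchSet
#' @param x a \linkS4class{PatchSet}.
#' @return Integer patch count L.
#' @export
nPatches <- function(x) nrow(x@patches)

#' Extract the patch matrix from a PatchSet
#' @param x a \linkS4class{PatchSet}.
#' @return The L x Nv numeric matrix.
#' @export
patchMatrix <- function(x) x@patches

#' Patch side length accessor
#' @param x a \linkS4class{PatchSet}.
#' @return Integer patch side in pixels.
#' @export
patchSide <- function(x) x@patchSide

#' Patch provenance accessor
#' @param x a \linkS4class{PatchSet}.
#' @return data.frame of (image, row, col) offsets per patch.
#' @export
patchProvenance <- function(x) x@provenance

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %dx%d (Nv = %d)\n",
              nrow(object@patches), object@patchSide, object@patchSide,
              ncol(object@patches)))
  if (nrow(object@patches)) {
    rng <- range(object@patches)
    cat(sprintf("  value range [%.4g, %.4g]\n", rng[1], rng[2]))
  }
  if (length(object@preprocessing))
    cat("  preprocessing:", paste(names(object@preprocessing),
                                  collapse = ", "), "\n")
})

#' Subset a PatchSet by patch index
#' @param x a PatchSet.
#' @param i integer or logical index over patches (rows).
#' @param j,drop,... ignored.
#' @export
setMethod("[", "PatchSet", function(x, i, j, ..., drop = FALSE) {
  new("PatchSet", patches = x@patches[i, , drop = FALSE],
      patchSide = x@patchSide,
      provenance = x@provenance[i, , drop = FALSE],
      preprocessing = x@preprocessing)
})

#' RBMModel: a binary restricted Boltzmann machine
#'
#' A two-layer bipartite Markov network over binary visible units v
#' (length Nv) and binary hidden units h (length Nh) with energy
#' E(v, h) = -t(v) W h - t(h) b - t(v) c. Columns of W are the basis
#' images of the hidden units.
#'
#' @slot W Nv x Nh numeric weight matrix.
#' @slot b length-Nh numeric hidden bias.
#' @slot c length-Nv numeric visible bias.
#'
#' @aliases RBMModel-class
#' @exportClass RBMModel
setClass("RBMModel",
  representation(W = "matrix", b = "numeric", c = "numeric")
)

setValidity("RBMModel", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@W)) || !all(is.finite(object@b)) ||
      !all(is.finite(object@c)))
    msg <- c(msg, "all parameters must be finite")
  if (nrow(object@W) < 1L || ncol(object@W) < 1L)
    msg <- c(msg, "W must be at least 1 x 1")
  if (length(object@b) != ncol(object@W))
    msg <- c(msg, "length(b) must equal ncol(W)")
  if (length(object@c) != nrow(object@W))
    msg <- c(msg, "length(c) must equal nrow(W)")
  if (length(msg)) msg else TRUE
})

#' Construct an RBM, either from explicit parameters or a seeded
#' random initialization
#'
#' With \code{W} given, wraps the supplied parameters. Otherwise draws
#' W from N(0, sd^2) with the given seed and zeroes both biases -- the
#' standard small-weight initialization.
#'
#' @param nVisible,nHidden layer sizes (used when W is NULL).
#' @param W optional Nv x Nh weight matrix.
#' @param b optional hidden bias (default 0).
#' @param c optional visible bias (default 0).
#' @param sd standard deviation of the Gaussian weight init.
#' @param seed integer seed for the random init.
#' @return An \linkS4class{RBMModel}.
#' @export
rbmModel <- function(nVisible = NULL, nHidden = NULL, W = NULL,
                     b = NULL, c = NULL, sd = 0.01, seed = 1L) {
  if (is.null(W)) {
    stopifnot(!is.null(nVisible), !is.null(nHidden))
    set.seed(as.integer(seed))
    W <- matrix(stats::rnorm(nVisible * nHidden, sd = sd),
                nVisible, nHidden)
  }
  W <- as.matrix(W)
  if (is.null(b)) b <- numeric(ncol(W))
  if (is.null(c)) c <- numeric(nrow(W))
  new("RBMModel", W = W, b = as.numeric(b), c = as.numeric(c))
}

#' Weight matrix accessor
#' @param object an \linkS4class{RBMModel}.
#' @return The Nv x Nh weight matrix.
#' @export
rbmWeights <- function(object) object@W

#' Hidden bias accessor
#' @param object an \linkS4class{RBMModel}.
#' @return Length-Nh numeric vector.
#' @export
hiddenBias <- function(object) object@b

#' Visible bias accessor
#' @param object an \linkS4class{RBMModel}.
#' @return Length-Nv numeric vector.
#' @export
visibleBias <- function(object) object@c

#' Number of visible units
#' @param object an \linkS4class{RBMModel}.
#' @return Integer Nv.
#' @export
nVisible <- function(object) nrow(object@W)

#' Number of hidden units
#' @param object an \linkS4class{RBMModel}.
#' @return Integer Nh.
#' @export
nHidden <- function(object) ncol(object@W)

setMethod("show", "RBMModel", function(object) {
  cat(sprintf("RBMModel: Nv = %d visible, Nh = %d hidden units\n",
              nrow(object@W), ncol(object@W)))
  cn <- sqrt(colSums(object@W^2))
  cat(sprintf("  column norms of W: [%.4g, %.4g]\n", min(cn), max(cn)))
})

#' TrainConfig: hyperparameters for RBM training
#'
#' @slot lambdaDiv non-negative weight of the diversity prior (lambda).
#' @slot C non-negative soft norm-penalty constant (only used when
#'   \code{renormalizeColumns} is FALSE).
#' @slot k number of block-Gibbs alternations in CD-k.
#' @slot learningRate positive step size.
#' @slot epochs number of full passes over the shuffled data.
#' @slot batchSize mini-batch size.
#' @slot seed integer seed controlling shuffling and Gibbs sampling.
#' @slot regularizer one of "none", "diversity", "sparse_group",
#'   "selective".
#' @slot renormalizeColumns if TRUE, every W column is rescaled to unit
#'   norm after each update (hard version of the unit-norm constraint).
#' @slot regWeight weight of the sparse_group / selective regularizers.
#' @slot targetActivation target mean activation for the selective
#'   regularizer.
#'
#' @aliases TrainConfig-class
#' @exportClass TrainConfig
setClass("TrainConfig",
  representation(
    lambdaDiv = "numeric", C = "numeric", k = "integer",
    learningRate = "numeric", epochs = "integer", batchSize = "integer",
    seed = "integer", regularizer = "character",
    renormalizeColumns = "logical", regWeight = "numeric",
    targetActivation = "numeric"
  )
)

setValidity("TrainConfig", function(object) {
  msg <- character(0)
  if (object@lambdaDiv < 0) msg <- c(msg, "lambdaDiv must be >= 0")
  if (object@C < 0) msg <- c(msg, "C must be >= 0")
  if (object@k < 1L) msg <- c(msg, "k must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@epochs < 0L) msg <- c(msg, "epochs must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (!object@regularizer %in%
      c("none", "diversity", "sparse_group", "selective"))
    msg <- c(msg, "unknown regularizer")
  if (object@targetActivation <= 0 || object@targetActivation >= 1)
    msg <- c(msg, "targetActivation must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a TrainConfig
#'
#' Defaults follow common CD practice: learning rate 0.05, batch size
#' 100, CD-1, no momentum, hard renormalization of W columns to unit
#' norm after every update.
#'
#' @param lambdaDiv diversity prior weight lambda (>= 0).
#' @param C soft norm-penalty constant (>= 0).
#' @param k CD steps (>= 1).
#' @param learningRate step size (> 0).
#' @param epochs number of epochs.
#' @param batchSize mini-batch size.
#' @param seed integer seed.
#' @param regularizer "none", "diversity", "sparse_group" or
#'   "selective".
#' @param renormalizeColumns hard unit-norm constraint on W columns.
#' @param regWeight weight of the comparison regularizers.
#' @param targetActivation target mean activation in (0,1) for the
#'   selective regularizer.
#' @return A \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(lambdaDiv = 1e-3, C = 1, k = 1L,
                        learningRate = 0.05, epochs = 400L,
                        batchSize = 100L, seed = 1L,
                        regularizer = "diversity",
                        renormalizeColumns = TRUE,
                        regWeight = 0.1, targetActivation = 0.02) {
  # Class= named explicitly: the C slot would otherwise partially
  # match new()'s Class formal
  new(Class = "TrainConfig", lambdaDiv = lambdaDiv, C = C,
      k = as.integer(k),
      learningRate = learningRate, epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), seed = as.integer(seed),
      regularizer = regularizer,
      renormalizeColumns = renormalizeColumns,
      regWeight = regWeight, targetActivation = targetActivation)
}

setMethod("show", "TrainConfig", function(object) {
  cat("TrainConfig:\n")
  cat(sprintf("  regularizer = %s, lambda = %g, C = %g\n",
              object@regularizer, object@lambdaDiv, object@C))
  cat(sprintf("  CD-%d, lr = %g, epochs = %d, batch = %d, seed = %d\n",
              object@k, object@learningRate, object@epochs,
              object@batchSize, object@seed))
  cat(sprintf("  renormalizeColumns = %s\n", object@renormalizeColumns))
})
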