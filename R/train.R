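# Mini-batch CD training with optional regularizers.

applyRegularizer <- function(model, batch, config) {
  switch(config@regularizer,
    none = list(dW = 0, db = 0, penalty = 0),
    diversity = {
      g <- diversityGradient(model@W, config@lambdaDiv,
                             if (config@renormalizeColumns) 0
                             else config@C)
      list(dW = g$dW, db = 0, penalty = g$penalty)
    },
    sparse_group = sparseGroupGradient(model@W, model@b, batch,
                                       config@regWeight),
    selective = selectiveGradient(model@W, model@b, batch,
                                  config@regWeight,
                                  config@targetActivation)
  )
}

#' Train an RBM with contrastive divergence and an optional
#' regularizer
#'
#' One epoch is one full pass over the (seeded) shuffled data in
#' mini-batches. Each update adds learningRate * (CD-k gradient +
#' regularizer gradient); if \code{renormalizeColumns} is set, every
#' weight column is rescaled to unit norm after the update (the hard
#' version of the unit-norm constraint on basis images). Training is
#' bit-reproducible given \code{config@seed}.
#'
#' @param model initial \linkS4class{RBMModel}.
#' @param patches a \linkS4class{PatchSet} or L x Nv matrix of
#'   preprocessed stimuli in [0, 1].
#' @param config a \linkS4class{TrainConfig}.
#' @return List with \code{model} (trained \linkS4class{RBMModel}) and
#'   \code{history}, a data.frame with one row per epoch: epoch number,
#'   mean per-pixel reconstruction cross-entropy, and the diversity
#'   penalty value of W at the end of the epoch.
#' @export
trainRBM <- function(model, patches, config) {
  V <- asPatchMatrix(patches)
  L <- nrow(V)
  if (L < 1L) stop("trainRBM: empty training set")
  validObject(model); validObject(config)
  set.seed(config@seed)
  W <- model@W; b <- model@b; cc <- model@c
  lr <- config@learningRate
  hist <- data.frame(epoch = integer(0), reconCrossEntropy = numeric(0),
                     diversityPenalty = numeric(0))
  for (ep in seq_len(config@epochs)) {
    ord <- sample.int(L)
    starts <- seq(1L, L, by = config@batchSize)
    ceSum <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config@batchSize - 1L, L)]
      batch <- V[idx, , drop = FALSE]
      m <- new("RBMModel", W = W, b = b, c = cc)
      cd <- cdGradient(m, batch, config@k)
      reg <- applyRegularizer(m, batch, config)
      W <- W + lr * (cd$dW + reg$dW)
      b <- b + lr * (cd$db + reg$db)
      cc <- cc + lr * cd$dc
      if (config@renormalizeColumns)
        W <- sweep(W, 2, colNorms(W), "/")
      if (!all(is.finite(W)) || !all(is.finite(b)) ||
          !all(is.finite(cc)))
        stop("trainRBM: parameters diverged (non-finite) at epoch ",
             ep, "; reduce the learning rate")
      p <- pmin(pmax(cd$vNeg, 1e-12), 1 - 1e-12)
      ceSum <- ceSum - sum(batch * log(p) + (1 - batch) * log(1 - p))
    }
    hist <- rbind(hist, data.frame(
      epoch = ep,
      reconCrossEntropy = ceSum / (L * ncol(V)),
      diversityPenalty = squaredCosinePenalty(W)))
  }
  list(model = new("RBMModel", W = W, b = b, c = cc), history = hist)
}
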