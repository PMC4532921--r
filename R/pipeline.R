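# End-to-end orchestration: preprocessing pipeline, lambda sweep and
# regularizer comparison experiments, and the two reference
# configurations (full scale and desk scale).

#' Full preprocessing pipeline: whiten, extract, sigmoid, filter
#'
#' Applies, in order: pseudo-whitening of every image, random patch
#' extraction, sigmoid rescaling of the pooled patches (z-scored over
#' all patch pixels jointly), and variance filtering.
#'
#' @param images list of grayscale images (numeric matrices).
#' @param nPatches number of patches to extract before filtering.
#' @param side patch side length (default 14).
#' @param f0,exponent whitening filter parameters.
#' @param gain sigmoid gain.
#' @param varThreshold variance threshold (default 0.1).
#' @param seed integer seed for patch extraction.
#' @return A preprocessed \linkS4class{PatchSet} (values in (0, 1)).
#' @export
preparePatches <- function(images, nPatches, side = 14L, f0 = 0.2,
                           exponent = 4, gain = 1, varThreshold = 0.1,
                           seed = 1L) {
  white <- lapply(images, whitenImage, f0 = f0, exponent = exponent)
  ps <- extractPatches(white, nPatches, side = side, seed = seed)
  ps <- sigmoidRescale(ps, gain = gain)
  ps <- filterLowVariance(ps, varThreshold)
  ps@preprocessing <- c(ps@preprocessing,
                        list(f0 = f0, exponent = exponent, gain = gain))
  ps
}

#' Prepare a target number of retained patches
#'
#' The variance filter keeps only the highest-contrast patches, so the
#' number surviving a single extraction pass is hard to predict. This
#' helper extracts patches in chunks (new seed-derived offsets each
#' chunk) and accumulates filtered patches until \code{nTarget} are
#' retained or \code{maxExtracted} raw patches have been drawn.
#'
#' @param images list of grayscale images.
#' @param nTarget number of retained patches wanted.
#' @param chunk raw patches per extraction chunk.
#' @param maxExtracted cap on total raw patches drawn.
#' @param ... passed to \code{\link{preparePatches}}.
#' @param seed integer seed.
#' @return A preprocessed \linkS4class{PatchSet} with at most
#'   \code{nTarget} patches (fewer, with a warning, if the cap is
#'   hit).
#' @export
prepareTargetPatches <- function(images, nTarget = 10000L,
                                 chunk = 50000L,
                                 maxExtracted = 1000000L, seed = 1L,
                                 ...) {
  got <- NULL
  drawn <- 0L
  i <- 0L
  while ((is.null(got) || nPatches(got) < nTarget) &&
         drawn < maxExtracted) {
    ps <- suppressWarnings(
      preparePatches(images, chunk, seed = seed + i, ...))
    drawn <- drawn + chunk
    got <- if (is.null(got)) ps else
      patchSet(rbind(patchMatrix(got), patchMatrix(ps)),
               patchSide = patchSide(ps),
               provenance = rbind(patchProvenance(got),
                                  patchProvenance(ps)),
               preprocessing = ps@preprocessing)
    i <- i + 1L
  }
  if (nPatches(got) < nTarget)
    warning("prepareTargetPatches: only ", nPatches(got),
            " patches retained after ", drawn, " raw draws")
  else
    got <- got[seq_len(nTarget)]
  got
}

#' Preprocess a whole image for reconstruction
#'
#' Whitens and sigmoid-rescales an image with the same parameters used
#' for training patches, so it can be fed to
#' \code{\link{reconstructImage}}.
#'
#' @param image numeric matrix.
#' @param f0,exponent whitening parameters.
#' @param gain sigmoid gain.
#' @return Preprocessed image in (0, 1).
#' @export
prepareImage <- function(image, f0 = 0.2, exponent = 4, gain = 1) {
  sigmoidRescale(whitenImage(image, f0 = f0, exponent = exponent),
                 gain = gain)
}

#' Full-scale reference configuration
#'
#' The configuration of the headline experiment: 14 x 14 patches
#' (Nv = 196), Nh = 200 hidden units, 100,000 patches, variance
#' threshold 0.1, diversity prior with lambda = 1e-3, 400 epochs of
#' CD-1.
#'
#' @param seed integer seed.
#' @return List with \code{nPatches}, \code{patchSide}, \code{nVisible},
#'   \code{nHidden}, \code{varThreshold} and \code{train} (a
#'   \linkS4class{TrainConfig}).
#' @export
fullScaleConfig <- function(seed = 1L) {
  list(nPatches = 100000L, patchSide = 14L, nVisible = 196L,
       nHidden = 200L, varThreshold = 0.1,
       train = trainConfig(lambdaDiv = 1e-3, k = 1L, epochs = 400L,
                           batchSize = 100L, learningRate = 0.05,
                           seed = seed, regularizer = "diversity"))
}

#' Desk-scale reference configuration
#'
#' A scaled-down configuration for desk experiments: 10,000 patches,
#' Nh = 50 hidden units, 50 epochs, otherwise identical to
#' \code{\link{fullScaleConfig}}.
#'
#' @param seed integer seed.
#' @return Same structure as \code{\link{fullScaleConfig}}.
#' @export
deskScaleConfig <- function(seed = 1L) {
  cfg <- fullScaleConfig(seed)
  cfg$nPatches <- 10000L
  cfg$nHidden <- 50L
  cfg$train@epochs <- 50L
  cfg
}

# Train one experiment arm and compute its summary metrics.
runArm <- function(init, patches, config, metricCap, deadThreshold,
                   seed) {
  fit <- tryCatch(trainRBM(init, patches, config),
                  error = function(e) e)
  if (inherits(fit, "error"))
    return(data.frame(meanSelectivity = NA_real_,
                      meanSparsity = NA_real_,
                      deadNeurons = NA_integer_, nStimuli = NA_integer_,
                      diversityPenalty = NA_real_,
                      failed = TRUE))
  m <- modelMetrics(fit$model, patches, cap = metricCap, seed = seed,
                    deadThreshold = deadThreshold)
  cbind(m,
        diversityPenalty = squaredCosinePenalty(rbmWeights(fit$model)),
        failed = FALSE)
}

#' Lambda sweep: train one diversity-prior RBM per lambda
#'
#' All arms share the same weight initialization and training seed, so
#' they differ only in the prior weight. Each arm reports mean
#' selectivity, mean sparsity, dead-neuron count and the final
#' squared-cosine penalty. An arm that diverges is marked failed and
#' the sweep continues.
#'
#' @param patches preprocessed \linkS4class{PatchSet}.
#' @param lambdas numeric vector of prior weights.
#' @param nHidden number of hidden units.
#' @param baseConfig \linkS4class{TrainConfig} template (its lambdaDiv
#'   and regularizer are overridden per arm).
#' @param metricCap stimulus cap for the metrics (default 5000).
#' @param deadThreshold dead-neuron threshold (default 0.1).
#' @param seed integer seed (weight init and metric subsample).
#' @return data.frame with one row per lambda.
#' @export
runLambdaSweep <- function(patches, lambdas = c(0, 1e-5, 1e-4, 1e-3,
                                                1e-2, 1e-1, 1),
                           nHidden = 50L,
                           baseConfig = trainConfig(epochs = 50L),
                           metricCap = 5000L, deadThreshold = 0.1,
                           seed = 1L) {
  nv <- ncol(patchMatrix(patches))
  init <- rbmModel(nv, nHidden, seed = seed)
  res <- lapply(lambdas, function(lam) {
    cfg <- baseConfig
    cfg@regularizer <- if (lam > 0) "diversity" else "none"
    cfg@lambdaDiv <- lam
    cbind(lambda = lam,
          runArm(init, patches, cfg, metricCap, deadThreshold, seed))
  })
  out <- do.call(rbind, res)
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Regularizer comparison: diversity vs sparse-group vs selective vs
#' none
#'
#' Trains four RBMs from a shared initialization, one per regularizer,
#' and reports the same summary columns as the lambda sweep. The
#' diversity and none arms inherit the template's column-norm
#' handling; the sparse-group and selective arms are trained
#' unconstrained, as the methods they reconstruct are plain CD RBMs
#' without a norm constraint (a unit-norm constraint would mask the
#' weight collapse that produces their characteristic dead neurons).
#' Arm weights default to values at which each regularizer visibly
#' shapes learning within the training schedule: the selective weight
#' is set so the mean activation actually reaches the neighborhood of
#' its target.
#'
#' @param patches preprocessed \linkS4class{PatchSet}.
#' @param nHidden number of hidden units.
#' @param baseConfig \linkS4class{TrainConfig} template.
#' @param lambdaDiv diversity prior weight for the diversity arm.
#' @param sparseWeight weight of the sparse-group (l1/l2) arm.
#' @param selectiveWeight weight of the selective arm.
#' @param metricCap,deadThreshold,seed as in
#'   \code{\link{runLambdaSweep}}.
#' @return data.frame with one row per arm (column \code{regularizer}).
#' @export
runRegularizerComparison <- function(patches, nHidden = 50L,
                                     baseConfig = trainConfig(epochs = 50L),
                                     lambdaDiv = 1e-3,
                                     sparseWeight = 1,
                                     selectiveWeight = 16,
                                     metricCap = 5000L,
                                     deadThreshold = 0.1, seed = 1L) {
  nv <- ncol(patchMatrix(patches))
  init <- rbmModel(nv, nHidden, seed = seed)
  arms <- c("diversity", "sparse_group", "selective", "none")
  res <- lapply(arms, function(arm) {
    cfg <- baseConfig
    cfg@regularizer <- arm
    cfg@lambdaDiv <- if (arm == "diversity") lambdaDiv else 0
    if (arm %in% c("sparse_group", "selective")) {
      cfg@regWeight <- if (arm == "sparse_group") sparseWeight
                       else selectiveWeight
      cfg@renormalizeColumns <- FALSE
    }
    cbind(regularizer = arm,
          runArm(init, patches, cfg, metricCap, deadThreshold, seed))
  })
  out <- do.call(rbind, res)
  attr(out, "seed") <- as.integer(seed)
  out
}
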