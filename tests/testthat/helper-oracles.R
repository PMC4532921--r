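# Shared oracles and fixture builders. All oracles here are written
# independently of the package internals (brute-force enumeration,
# naive loops, central finite differences) so they can validate the
# vectorized implementations.

# A random tiny RBM with all parameters drawn fresh.
randomTinyRBM <- function(nv, nh, scale = 1) {
  rbmModel(W = matrix(rnorm(nv * nh, sd = scale), nv, nh),
           b = rnorm(nh, sd = scale), c = rnorm(nv, sd = scale))
}

# All binary vectors of length n as rows of a 2^n x n matrix.
allBinary <- function(n) {
  as.matrix(do.call(expand.grid, rep(list(c(0, 1)), n)))
}

# Brute-force mean log-likelihood by full 2^(Nv+Nh) enumeration.
bruteLogLik <- function(model, V) {
  W <- rbmWeights(model); b <- hiddenBias(model); cc <- visibleBias(model)
  sv <- allBinary(nrow(W)); sh <- allBinary(ncol(W))
  En <- function(v, h) -as.numeric(t(v) %*% W %*% h) - sum(h * b) -
    sum(v * cc)
  Z <- 0
  for (i in seq_len(nrow(sv))) for (j in seq_len(nrow(sh)))
    Z <- Z + exp(-En(sv[i, ], sh[j, ]))
  ll <- apply(V, 1, function(v) {
    pv <- 0
    for (j in seq_len(nrow(sh))) pv <- pv + exp(-En(v, sh[j, ]))
    log(pv) - log(Z)
  })
  mean(ll)
}

# Central finite differences of a scalar function of an RBM's
# parameters, w.r.t. every parameter, returned as dW/db/dc.
fdGradientRBM <- function(fun, model, eps = 1e-5) {
  W <- rbmWeights(model); b <- hiddenBias(model); cc <- visibleBias(model)
  mk <- function(W, b, cc) rbmModel(W = W, b = b, c = cc)
  dW <- W * 0
  for (i in seq_along(W)) {
    Wp <- W; Wm <- W; Wp[i] <- Wp[i] + eps; Wm[i] <- Wm[i] - eps
    dW[i] <- (fun(mk(Wp, b, cc)) - fun(mk(Wm, b, cc))) / (2 * eps)
  }
  db <- b * 0
  for (i in seq_along(b)) {
    bp <- b; bm <- b; bp[i] <- bp[i] + eps; bm[i] <- bm[i] - eps
    db[i] <- (fun(mk(W, bp, cc)) - fun(mk(W, bm, cc))) / (2 * eps)
  }
  dc <- cc * 0
  for (i in seq_along(cc)) {
    cp <- cc; cm <- cc; cp[i] <- cp[i] + eps; cm[i] <- cm[i] - eps
    dc[i] <- (fun(mk(W, b, cp)) - fun(mk(W, b, cm))) / (2 * eps)
  }
  list(dW = dW, db = db, dc = dc)
}

# Central finite differences of a scalar function of a matrix.
fdGradientMatrix <- function(fun, W, eps = 1e-6) {
  g <- W * 0
  for (i in seq_along(W)) {
    Wp <- W; Wm <- W; Wp[i] <- Wp[i] + eps; Wm[i] <- Wm[i] - eps
    g[i] <- (fun(Wp) - fun(Wm)) / (2 * eps)
  }
  g
}

# Naive O(Nh^2) double loop over ordered pairs of columns.
naiveCosinePenalty <- function(W) {
  nh <- ncol(W)
  s <- 0
  for (j in seq_len(nh)) for (k in seq_len(nh)) {
    if (j == k) next
    cjk <- sum(W[, j] * W[, k]) /
      (sqrt(sum(W[, j]^2)) * sqrt(sum(W[, k]^2)))
    s <- s + cjk^2
  }
  s
}

# Exact expectation of the CD-1 weight gradient for a fixed visible
# vector: the only randomness is the binary draw of h+, so enumerate
# all 2^Nh hidden samples with their Bernoulli probabilities.
enumCD1ExpectationW <- function(model, v) {
  ph <- probHiddenGivenVisible(model, v)
  H <- allBinary(nHidden(model))
  EdW <- matrix(0, nVisible(model), nHidden(model))
  for (j in seq_len(nrow(H))) {
    h <- H[j, ]
    pr <- prod(ifelse(h == 1, ph, 1 - ph))
    vneg <- probVisibleGivenHidden(model, h)
    phneg <- probHiddenGivenVisible(model, vneg)
    EdW <- EdW + pr * (outer(v, ph) - outer(vneg, phneg))
  }
  EdW
}

# Small preprocessed synthetic patch set, cached per session.
smallPatchFixture <- local({
  cache <- NULL
  function(n = 500, seed = 11) {
    if (!is.null(cache)) return(cache)
    imgs <- syntheticImages(4, 70, seed = seed)
    cache <<- prepareTargetPatches(imgs, nTarget = n, chunk = 10000L,
                                   maxExtracted = 200000L, seed = seed)
    cache
  }
})
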