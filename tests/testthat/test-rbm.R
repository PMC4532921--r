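# RBM energy, conditionals, exact oracles and the CD-k estimator.

test_that("energy matches hand arithmetic and rejects bad shapes", {
  m0 <- rbmModel(W = matrix(0, 2, 3), b = rep(1, 3), c = rep(0, 2))
  expect_equal(rbmEnergy(m0, c(0, 0), c(0, 0, 0)), 0)
  expect_equal(rbmEnergy(m0, c(0, 0), c(1, 1, 1)), -3)  # -Nh from b

  m <- rbmModel(W = matrix(c(1, 2), 2, 1), b = 0.5, c = c(0, 0))
  expect_equal(rbmEnergy(m, c(1, 1), 1), -3.5)
  expect_error(rbmEnergy(m, c(1, 1, 1), 1), "dimensions")
})

test_that("conditional probabilities are logistic in the
           pre-activation and factorize", {
  m0 <- rbmModel(W = matrix(0, 3, 2), b = c(0, 0), c = rep(0, 3))
  expect_equal(probHiddenGivenVisible(m0, c(1, 0, 1)), c(0.5, 0.5))
  expect_equal(probVisibleGivenHidden(m0, c(1, 0)), rep(0.5, 3))

  mBig <- rbmModel(W = matrix(0, 2, 1), b = 50, c = c(0, 0))
  expect_gt(probHiddenGivenVisible(mBig, c(0, 0)), 1 - 1e-12)

  # zero pre-activation is exactly 0.5
  m <- rbmModel(W = matrix(c(1, -1), 2, 1), b = 0, c = c(0, 0))
  expect_equal(probHiddenGivenVisible(m, c(0.5, 0.5)), 0.5)

  # joint conditional equals the product of marginals on an
  # enumerable instance: check via the exact joint
  set.seed(7)
  mm <- randomTinyRBM(3, 2)
  v <- c(1, 0, 1)
  ph <- probHiddenGivenVisible(mm, v)
  H <- allBinary(2)
  En <- function(h) exp(-rbmEnergy(mm, v, h))
  Z <- sum(apply(H, 1, En))
  for (j in seq_len(nrow(H))) {
    pJoint <- En(H[j, ]) / Z
    pProd <- prod(ifelse(H[j, ] == 1, ph, 1 - ph))
    expect_equal(pJoint, pProd, tolerance = 1e-12)
  }
})

test_that("exact log-likelihood agrees with full 2^(Nv+Nh)
           enumeration and with closed forms at zero parameters", {
  m0 <- rbmModel(W = matrix(0, 1, 1), b = 0, c = 0)
  expect_equal(exactLogLikelihood(m0, 1), log(0.5))
  m03 <- rbmModel(W = matrix(0, 3, 2), b = c(0, 0), c = rep(0, 3))
  expect_equal(exactLogLikelihood(m03, c(1, 0, 1)), -3 * log(2))

  set.seed(12)
  for (rep in 1:5) {
    nv <- sample(2:4, 1); nh <- sample(1:3, 1)
    mm <- randomTinyRBM(nv, nh)
    V <- allBinary(nv)[sample.int(2^nv, 3), , drop = FALSE]
    expect_equal(exactLogLikelihood(mm, V), bruteLogLik(mm, V),
                 tolerance = 1e-10)
  }

  big <- rbmModel(nVisible = 25, nHidden = 25, seed = 1)
  expect_error(exactLogLikelihood(big, rep(0, 25)), "guard")
})

test_that("exact gradient matches finite differences and the
           zero-parameter closed form", {
  set.seed(13)
  for (rep in 1:3) {
    mm <- randomTinyRBM(3, 2, scale = 0.8)
    V <- matrix(runif(4 * 3), 4, 3)     # real-valued visibles allowed
    g <- exactGradient(mm, V)
    fd <- fdGradientRBM(function(m) exactLogLikelihood(m, V), mm)
    expect_equal(g$dW, fd$dW, tolerance = 1e-6)
    expect_equal(g$db, fd$db, tolerance = 1e-6)
    expect_equal(g$dc, fd$dc, tolerance = 1e-6)
  }

  # at all-zero parameters dc = mean(v) - 1/2
  m0 <- rbmModel(W = matrix(0, 3, 2), b = c(0, 0), c = rep(0, 3))
  V <- matrix(c(1, 0, 1, 1, 1, 0), 2, 3)
  g0 <- exactGradient(m0, V)
  expect_equal(g0$dc, colMeans(V) - 0.5, tolerance = 1e-12)
})

test_that("CD gradient is seed-reproducible, respects batch averaging
           and rejects empty batches", {
  set.seed(14)
  mm <- randomTinyRBM(4, 3)
  v <- runif(4)
  set.seed(99); g1 <- cdGradient(mm, v, k = 1)
  set.seed(99); g2 <- cdGradient(mm, v, k = 1)
  expect_identical(g1$dW, g2$dW)

  batch <- matrix(rep(v, 5), 5, 4, byrow = TRUE)
  set.seed(99); gb <- cdGradient(mm, batch, k = 1)
  # identical rows: same expectation; with a shared seed each row sees
  # independent draws, so compare expectations over draws instead
  expect_equal(dim(gb$dW), dim(g1$dW))
  expect_error(cdGradient(mm, matrix(0, 0, 4)), "empty")
  expect_error(cdGradient(mm, v, k = 0), "k must be")
})

test_that("CD-1 weight gradient is unbiased against the enumerated
           expectation on a tiny RBM", {
  set.seed(15)
  mm <- randomTinyRBM(3, 2)
  v <- c(1, 0, 1)
  EdW <- enumCD1ExpectationW(mm, v)
  n <- 2000
  draws <- array(0, c(3, 2, n))
  set.seed(16)
  for (i in seq_len(n)) draws[, , i] <- cdGradient(mm, v, k = 1)$dW
  mn <- apply(draws, c(1, 2), mean)
  se <- apply(draws, c(1, 2), sd) / sqrt(n)
  expect_true(all(abs(mn - EdW) <= 3 * pmax(se, 1e-12)))
})

test_that("CD-k approaches the exact gradient as k grows", {
  set.seed(17)
  mm <- randomTinyRBM(3, 2, scale = 0.5)
  V <- allBinary(3)[c(2, 5, 7), ]
  gx <- exactGradient(mm, V)
  err <- sapply(c(1, 20), function(k) {
    set.seed(18)
    acc <- 0
    for (i in 1:400) acc <- acc + cdGradient(mm, V, k = k)$dW
    max(abs(acc / 400 - gx$dW))
  })
  # longer chains reduce the CD bias
  expect_lt(err[2], err[1] + 0.02)
  expect_lt(err[2], 0.1)
})

test_that("training with the exact gradient ascends the likelihood
           and zero epochs is the identity", {
  set.seed(19)
  V <- allBinary(4)[sample.int(16, 6), ]
  mm <- randomTinyRBM(4, 2, scale = 0.3)
  ll <- exactLogLikelihood(mm, V)
  for (it in 1:30) {
    g <- exactGradient(mm, V)
    mm <- rbmModel(W = rbmWeights(mm) + 0.2 * g$dW,
                   b = hiddenBias(mm) + 0.2 * g$db,
                   c = visibleBias(mm) + 0.2 * g$dc)
    llNew <- exactLogLikelihood(mm, V)
    expect_gte(llNew, ll - 1e-9)
    ll <- llNew
  }

  cfg0 <- trainConfig(epochs = 0L, seed = 5)
  init <- rbmModel(4, 2, seed = 5)
  out <- trainRBM(init, V, cfg0)
  expect_identical(rbmWeights(out$model), rbmWeights(init))
  expect_equal(nrow(out$history), 0L)
})

test_that("training is bit-reproducible given the config seed", {
  ps <- smallPatchFixture()
  cfg <- trainConfig(epochs = 2L, seed = 31, lambdaDiv = 1e-3)
  init <- rbmModel(196, 8, seed = 31)
  a <- trainRBM(init, ps, cfg)
  b <- trainRBM(init, ps, cfg)
  expect_identical(rbmWeights(a$model), rbmWeights(b$model))
  expect_identical(a$history, b$history)
  # history is monotone in epoch and finite
  expect_equal(a$history$epoch, seq_len(2))
  expect_true(all(is.finite(a$history$reconCrossEntropy)))
})

test_that("model serialization round-trips bit-exactly", {
  set.seed(20)
  mm <- randomTinyRBM(5, 3)
  path <- tempfile()
  writeRBMModel(mm, path, metadata = list(note = "roundtrip"))
  back <- readRBMModel(path)
  expect_identical(rbmWeights(back), rbmWeights(mm))
  expect_identical(hiddenBias(back), hiddenBias(mm))
  expect_identical(visibleBias(back), visibleBias(mm))
})
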