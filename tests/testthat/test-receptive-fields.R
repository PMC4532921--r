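# Reverse-correlation receptive fields, Gabor fitting and shape
# profiles.

test_that("reverse-correlation RF reduces to the weighted stimulus
           sum and is linear in the ensemble", {
  m0 <- rbmModel(W = matrix(0, 9, 2), b = c(0, 0), c = rep(0, 9))
  V <- matrix(runif(5 * 9), 5, 9)
  ps <- patchSet(V, patchSide = 3)
  rf <- estimateRF(m0, ps, 1)
  expect_equal(as.numeric(rf), 0.5 * colSums(V))  # all weights 0.5

  set.seed(41)
  mm <- randomTinyRBM(9, 2)
  one <- estimateRF(mm, patchSet(V[3, , drop = FALSE], patchSide = 3), 2)
  p <- probHiddenGivenVisible(mm, V[3, ])[2]
  expect_equal(as.numeric(one), p * V[3, ])

  # permutation invariance over stimuli
  expect_equal(estimateRF(mm, patchSet(V[c(4, 1, 5, 2, 3), ],
                                       patchSide = 3), 1),
               estimateRF(mm, ps, 1))

  # estimateRFs columns agree with per-unit calls
  RF <- estimateRFs(mm, ps)
  expect_equal(matrix(RF[, 2], 3, 3), estimateRF(mm, ps, 2))
  RFc <- estimateRFs(mm, ps, centered = TRUE)
  expect_equal(matrix(RFc[, 1], 3, 3),
               estimateRF(mm, ps, 1, centered = TRUE))
})

test_that("in the near-linear regime the centered RF aligns with the
           stimulus-covariance-weighted weight column", {
  set.seed(42)
  nv <- 16
  W <- matrix(rnorm(nv * 2, sd = 1e-3), nv, 2)  # tiny weights
  mm <- rbmModel(W = W, b = c(0, 0), c = rep(0, nv))
  V <- matrix(runif(4000 * nv), 4000, nv)       # near-white stimuli
  rf <- as.numeric(estimateRF(mm, patchSet(V, patchSide = 4), 1,
                              centered = TRUE, cap = Inf))
  # linearization: RF ~ S * Cov(v) W[,1] / 4; white stimuli make Cov
  # diagonal, so direction matches W[,1]
  cosang <- sum(rf * W[, 1]) / sqrt(sum(rf^2) * sum(W[, 1]^2))
  expect_gt(cosang, 0.95)
})

test_that("RF / basis-image agreement is a correlation with the
           expected sign conventions", {
  set.seed(43)
  basis <- rnorm(25)
  expect_equal(rfBasisAgreement(basis, basis), 1)
  expect_equal(rfBasisAgreement(3 * basis + 2, basis), 1)
  expect_equal(rfBasisAgreement(-basis, basis), -1)
  ortho <- rnorm(25)
  ortho <- ortho - mean(ortho)
  bc <- basis - mean(basis)
  ortho <- ortho - sum(ortho * bc) / sum(bc^2) * bc
  expect_equal(rfBasisAgreement(ortho, basis), 0, tolerance = 1e-12)
  expect_warning(r0 <- rfBasisAgreement(rep(1, 25), basis), "variance")
  expect_equal(r0, 0)
})

test_that("noiseless synthetic Gabors are recovered across an
           orientation x frequency grid", {
  for (thetaDeg in c(0, 30, 60, 90)) {
    for (f in c(0.1, 0.2, 0.3)) {
      truth <- gaborImage(14, 7.2, 7.8, 1, 2.5, 3.5,
                          thetaDeg * pi / 180, f, 0.4)
      fit <- fitGabor(truth, nRestarts = 8, seed = 7)
      expect_gt(fit$r2, 0.99)
      dTheta <- min(abs(fit$theta - thetaDeg * pi / 180),
                    pi - abs(fit$theta - thetaDeg * pi / 180))
      expect_lt(dTheta, 5 * pi / 180)
      expect_lt(abs(fit$f - f) / f, 0.05)
    }
  }
})

test_that("Gabor recovery tolerates noise at SNR 10 in the median", {
  truth <- gaborImage(14, 7.5, 7.5, 1, 3, 4, pi / 3, 0.18, -0.5)
  sdNoise <- sd(as.vector(truth)) / sqrt(10)
  set.seed(44)
  dTheta <- dF <- numeric(20)
  for (i in 1:20) {
    noisy <- truth + matrix(rnorm(196, sd = sdNoise), 14, 14)
    fit <- fitGabor(noisy, nRestarts = 6, seed = i)
    dTheta[i] <- min(abs(fit$theta - pi / 3),
                     pi - abs(fit$theta - pi / 3))
    dF[i] <- abs(fit$f - 0.18) / 0.18
  }
  expect_lt(median(dTheta), 15 * pi / 180)
  expect_lt(median(dF), 0.15)
})

test_that("Gabor fitting is seed-reproducible, improves with
           restarts, and survives model mismatch", {
  truth <- gaborImage(14, 7, 8, 1, 3, 3, 0.7, 0.15, 0)
  a <- fitGabor(truth, nRestarts = 5, seed = 9)
  b <- fitGabor(truth, nRestarts = 5, seed = 9)
  expect_identical(a, b)
  few <- fitGabor(truth, nRestarts = 1, seed = 9)
  expect_gte(a$r2, few$r2 - 1e-9)

  # pure Gaussian blob: no representable frequency; must not crash
  blob <- gaborImage(14, 7.5, 7.5, 1, 2.5, 2.5, 0, 1e-6, 0)
  fit <- fitGabor(blob, nRestarts = 4, seed = 10)
  expect_true(is.finite(fit$r2) || fit$r2 == -Inf)

  expect_error(fitGabor(matrix(1, 14, 14)), "constant")
})

test_that("canonical ranges: theta in [0, pi), phi in [-pi, pi),
           positive amplitude and widths", {
  set.seed(45)
  for (i in 1:5) {
    truth <- gaborImage(14, runif(1, 5, 9), runif(1, 5, 9), 1,
                        runif(1, 2, 4), runif(1, 2, 4),
                        runif(1, 0, pi), runif(1, 0.1, 0.3),
                        runif(1, -pi, pi))
    fit <- fitGabor(truth, nRestarts = 6, seed = i)
    expect_gte(fit$theta, 0); expect_lt(fit$theta, pi)
    expect_gte(fit$phi, -pi); expect_lt(fit$phi, pi)
    expect_gt(fit$A, 0)
    expect_gt(fit$sigmaX, 0); expect_gt(fit$sigmaY, 0)
  }
})

test_that("quality filter applies the r2 rule and sanity bounds", {
  fits <- data.frame(unit = 1:3, x0 = c(7, 7, 7), y0 = c(7, 7, 7),
                     A = 1, sigmaX = 3, sigmaY = 3, theta = 0,
                     f = 0.2, phi = 0,
                     r2 = c(0.2, 0.6, 0.9), converged = TRUE)
  kept <- qualityFilter(fits, r2Min = 0.5, side = 14)
  expect_equal(kept$unit, c(2, 3))
  expect_equal(nrow(qualityFilter(fits, r2Min = 0,
                                  sanityBounds = FALSE)), 3)
  # out-of-patch center and oversized envelope are rejected
  bad <- fits
  bad$x0[3] <- 40
  bad$sigmaX[2] <- 100
  expect_equal(nrow(qualityFilter(bad, r2Min = 0, side = 14)), 1)
  expect_error(qualityFilter(fits, r2Min = 2), "r2Min")
})

test_that("shape profiles are dimensionless and the aspect histogram
           counts every fit", {
  fits <- data.frame(unit = 1:4, sigmaX = c(2, 3, 4, 2),
                     sigmaY = c(2, 6, 2, 3),
                     f = c(0.2, 0.1, 0.15, 0.25))
  pr <- shapeProfiles(fits)
  expect_equal(pr$nx, fits$sigmaX * fits$f)
  expect_equal(pr$aspectRatio[1], 1)             # sigmaX == sigmaY
  # doubling sigma while halving f leaves (nx, ny) unchanged
  fits2 <- fits; fits2$sigmaX <- 2 * fits$sigmaX
  fits2$sigmaY <- 2 * fits$sigmaY; fits2$f <- fits$f / 2
  expect_equal(shapeProfiles(fits2)$nx, pr$nx)
  expect_equal(shapeProfiles(fits2)$ny, pr$ny)
  # both ratio orientations
  expect_equal(shapeProfiles(fits, ratio = "nx/ny")$aspectRatio,
               1 / pr$aspectRatio)
  h <- aspectHistogram(pr)
  expect_equal(sum(h$count), nrow(fits))
  # out-of-range values are still counted
  h2 <- aspectHistogram(data.frame(aspectRatio = c(0.5, 99)),
                        binEdges = c(0, 1, 2))
  expect_equal(sum(h2$count), 2)
})
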