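# Diversity prior: squared-cosine penalty, its gradient, and the
# sparse-group / selectivity comparison regularizers.

test_that("squared-cosine penalty has the analytic values on
           orthogonal and parallel columns", {
  expect_equal(squaredCosinePenalty(diag(4)), 0)
  W2 <- cbind(c(1, 2, 3), c(1, 2, 3))         # two identical columns
  expect_equal(squaredCosinePenalty(W2), 2)   # two ordered pairs
  # all columns identical: Nh (Nh - 1)
  W5 <- matrix(rep(c(1, -1, 0.5), 5), 3, 5)
  expect_equal(squaredCosinePenalty(W5), 5 * 4)
})

test_that("vectorized penalty equals the naive ordered-pair loop and
           respects its invariances", {
  set.seed(23)
  for (rep in 1:5) {
    W <- matrix(rnorm(20), 5, 4)
    expect_equal(squaredCosinePenalty(W), naiveCosinePenalty(W),
                 tolerance = 1e-12)
    # permutation, sign flip, per-column rescale invariance
    expect_equal(squaredCosinePenalty(W[, c(3, 1, 4, 2)]),
                 squaredCosinePenalty(W), tolerance = 1e-12)
    Wf <- W; Wf[, 2] <- -Wf[, 2]
    expect_equal(squaredCosinePenalty(Wf), squaredCosinePenalty(W),
                 tolerance = 1e-12)
    Ws <- sweep(W, 2, c(0.1, 3, 7, 0.5), "*")
    expect_equal(squaredCosinePenalty(Ws), squaredCosinePenalty(W),
                 tolerance = 1e-10)
    # bounds
    p <- squaredCosinePenalty(W)
    expect_gte(p, 0); expect_lte(p, 4 * 3)
  }
  expect_error(squaredCosinePenalty(cbind(c(0, 0), c(1, 1)),
                                    epsGuard = FALSE), "zero-norm")
})

test_that("normalized and unnormalized penalty forms agree on
           unit-norm matrices", {
  set.seed(24)
  for (rep in 1:5) {
    W <- matrix(rnorm(24), 6, 4)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    unnorm <- sum(crossprod(W)^2) - ncol(W)  # (t(Wj) Wk)^2, j != k
    expect_equal(squaredCosinePenalty(W), unnorm, tolerance = 1e-10)
  }
})

test_that("prior log density is -lambda times the penalty and linear
           in lambda", {
  set.seed(25)
  W <- matrix(rnorm(15), 5, 3)
  expect_equal(priorLogDensity(W, 0.2),
               -0.2 * squaredCosinePenalty(W))
  expect_equal(priorLogDensity(W, 0.4), 2 * priorLogDensity(W, 0.2))
  expect_equal(priorLogDensity(diag(3), 5), 0)
})

test_that("diversity gradient matches finite differences of the
           unnormalized penalty plus soft norm term", {
  set.seed(26)
  for (rep in 1:4) {
    W <- matrix(rnorm(20), 5, 4)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")   # unit-norm columns
    lam <- 0.3; C <- 0.7
    obj <- function(W) {
      G <- crossprod(W)
      -lam * (sum(G^2) - sum(diag(G)^2)) -
        lam * C * sum((sqrt(colSums(W^2)) - 1)^2)
    }
    g <- diversityGradient(W, lam, C)
    fd <- fdGradientMatrix(obj, W)
    expect_equal(g$dW, fd, tolerance = 1e-6)
  }
  # off unit norm the C-term engages; check fd there too
  W <- matrix(rnorm(12), 4, 3) * 1.7
  lam <- 0.1; C <- 2
  obj <- function(W) {
    G <- crossprod(W)
    -lam * (sum(G^2) - sum(diag(G)^2)) -
      lam * C * sum((sqrt(colSums(W^2)) - 1)^2)
  }
  expect_equal(diversityGradient(W, lam, C)$dW,
               fdGradientMatrix(obj, W), tolerance = 1e-6)
})

test_that("diversity gradient vanishes where it should", {
  expect_equal(diversityGradient(matrix(rnorm(12), 4, 3), 0)$dW,
               matrix(0, 4, 3))
  # unit-norm orthogonal columns are a stationary point
  g <- diversityGradient(diag(4)[, 1:3], 0.5, C = 1)
  expect_equal(g$dW, matrix(0, 4, 3), tolerance = 1e-12)
  expect_equal(g$penalty, 0)
})

test_that("an infinitesimal step along the diversity gradient never
           increases the penalty", {
  set.seed(27)
  for (rep in 1:5) {
    W <- matrix(rnorm(30), 6, 5)
    W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
    g <- diversityGradient(W, 1, C = 0)
    pen0 <- squaredCosinePenalty(W)
    pen1 <- squaredCosinePenalty(W + 1e-4 * g$dW)
    expect_lte(pen1, pen0 + 1e-12)
  }
})

test_that("sparse-group gradient matches finite differences and its
           analytic special cases", {
  set.seed(28)
  W <- matrix(rnorm(12, sd = 0.5), 4, 3)
  b <- rnorm(3, sd = 0.5)
  V <- matrix(runif(5 * 4), 5, 4)
  wgt <- 0.3
  g <- sparseGroupGradient(W, b, V, wgt)
  penalty <- function(W, b) {
    P <- plogis(sweep(V %*% W, 2, b, "+"))
    -wgt * mean(rowSums(P) / sqrt(rowSums(P^2)))
  }
  fdW <- fdGradientMatrix(function(W) penalty(W, b), W)
  expect_equal(g$dW, fdW, tolerance = 1e-6)
  fdB <- sapply(seq_along(b), function(i) {
    e <- 1e-6; bp <- b; bm <- b
    bp[i] <- bp[i] + e; bm[i] <- bm[i] - e
    (penalty(W, bp) - penalty(W, bm)) / (2 * e)
  })
  expect_equal(g$db, fdB, tolerance = 1e-6)

  expect_equal(sparseGroupGradient(W, b, V, 0)$dW, matrix(0, 4, 3))
  # a one-hot activation row attains the l1/l2 minimum of 1
  Wsat <- matrix(c(50, -50, -50), 1, 3)
  g1 <- sparseGroupGradient(Wsat, c(0, -50, -50), matrix(1, 1, 1), 1)
  expect_equal(g1$penalty, 1, tolerance = 1e-6)
})

test_that("selective gradient matches finite differences and is zero
           at the target activation", {
  set.seed(29)
  W <- matrix(rnorm(12, sd = 0.5), 4, 3)
  b <- rnorm(3, sd = 0.5)
  V <- matrix(runif(6 * 4), 6, 4)
  wgt <- 0.4; tgt <- 0.2
  g <- selectiveGradient(W, b, V, wgt, tgt)
  penalty <- function(W, b) {
    P <- plogis(sweep(V %*% W, 2, b, "+"))
    -wgt * sum((colMeans(P) - tgt)^2)
  }
  expect_equal(g$dW, fdGradientMatrix(function(W) penalty(W, b), W),
               tolerance = 1e-6)

  expect_equal(selectiveGradient(W, b, V, 0, tgt)$dW, matrix(0, 4, 3))
  # mean activation exactly at target: gradient vanishes
  g0 <- selectiveGradient(matrix(0, 4, 2), qlogis(c(0.2, 0.2)),
                          V, 1, 0.2)
  expect_equal(g0$dW, matrix(0, 4, 2), tolerance = 1e-12)
  expect_equal(g0$penalty, 0, tolerance = 1e-12)
})
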