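test_that("meanCenter subtracts and stores the row means", {
  tm <- meanCenter(matrix(c(1, 2, 3, 2), 2))
  expect_equal(trainingData(tm), matrix(c(-1, 0, 1, 0), 2))
  expect_equal(centerVector(tm), c(2, 2))

  z <- matrix(c(-1, 1, 1, -1), 2)
  tm0 <- meanCenter(z)
  expect_equal(trainingData(tm0), z)
  expect_equal(centerVector(tm0), c(0, 0))

  one <- matrix(c(3, 5), 2, 1)
  tm1 <- meanCenter(one)
  expect_equal(trainingData(tm1), matrix(0, 2, 1))
  expect_equal(centerVector(tm1), c(3, 5))

  expect_error(meanCenter(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("L1 objective, sign and soft-threshold follow their definitions", {
  X <- cbind(c(2, 0), c(0, 1))
  expect_equal(l1Objective(X, c(1, 0)), 2)
  expect_equal(l1Objective(X, c(0, 0)), 0)
  w <- c(0.3, -0.9)
  expect_equal(l1Objective(X, w), l1Objective(X, -w))
  expect_error(l1Objective(X, c(1, 2, 3)), "length")

  expect_equal(signVec(c(3, -0.5, 0)), c(1, -1, 0))
  expect_equal(signVec(-c(3, -0.5, 0)), -signVec(c(3, -0.5, 0)))

  expect_equal(softThreshold(c(3, -0.5), 1), c(2, 0))
  v <- c(-2, 0.3, 1.7)
  expect_equal(softThreshold(v, 0), v)
  expect_equal(softThreshold(v, max(abs(v))), c(0, 0, 0))
  expect_error(softThreshold(v, -1), "nonnegative")
})

test_that("L2 baseline returns ordered orthonormal eigenvectors", {
  X <- cbind(c(1, 1), c(-1, -1))
  b <- pcaComponents(X, 1)
  expect_equal(basisMatrix(b)[, 1], c(1, 1) / sqrt(2), tolerance = 1e-8)

  Xf <- randomStack(6, 20, seed = 21)
  bf <- pcaComponents(Xf, 6)
  W <- basisMatrix(bf)
  expect_equal(W %*% t(W), diag(6), tolerance = 1e-8)
  expect_error(pcaComponents(Xf, 7), "at most")

  # minimal training reconstruction error among r-dim bases (L2 optimality)
  Xc <- trainingData(meanCenter(randomStack(10, 25, seed = 22)))
  b3 <- pcaComponents(Xc, 3)
  errPCA <- reconstructionError(b3, t(Xc))
  for (s in 1:15) {
    Wr <- randomOrthonormal(10, 3, seed = 100 + s)
    expect_gt(reconstructionError(Wr, t(Xc)), errPCA)
  }
})

test_that("L1 power iteration has the hand-computed fixed points", {
  X <- cbind(c(2, 0), c(0, 1))
  cfg <- solverConfig("pca_l1")
  r1 <- pcaL1Component(X, c(1, 0), cfg)
  expect_equal(componentVector(r1), c(1, 0))
  expect_equal(max(objectiveTrajectory(r1)), 2)
  expect_true(r1@converged)

  # the other axis is a genuine local optimum: initialization matters
  r2 <- pcaL1Component(X, c(0, 1), cfg)
  expect_equal(componentVector(r2), c(0, 1))
  expect_equal(max(objectiveTrajectory(r2)), 1)

  # degenerate v = 0: flagged, vector unchanged
  Xd <- cbind(c(1, 0), c(-1, 0))
  rd <- pcaL1Component(Xd, c(0, 1), cfg)
  expect_false(rd@converged)
  expect_equal(componentVector(rd), c(0, 1))
  expect_error(pcaL1Component(X, c(2, 0), cfg), "unit")
})

test_that("relaxed RSPCA update reproduces the hand-worked shrinkage step", {
  # single image x = (4, 1), w0 = (0.8, 0.6): v = x, u = (4*0.8/1.8, 1*0.6/1.6)
  X <- matrix(c(4, 1), 2, 1)
  w0 <- c(0.8, 0.6)
  cfg <- solverConfig("rspca_relaxed", eta1 = 1, maxIter = 1L)
  res <- rspcaComponent(X, w0, cfg)
  uHand <- c(4 * 0.8 / 1.8, 1 * 0.6 / 1.6)
  expect_equal(uHand, c(1.7778, 0.3750), tolerance = 1e-4)
  expect_equal(componentVector(res), uHand / sqrt(sum(uHand^2)))
})

test_that("both RSPCA rules reduce to PCA-L1 at zero shrinkage", {
  X <- trainingData(meanCenter(randomStack(15, 12, seed = 31)))
  w0 <- leadVector(X)
  ref <- pcaL1Component(X, w0, solverConfig("pca_l1"))
  soft <- rspcaComponent(X, w0, solverConfig("rspca_soft", lambdaSoft = 0))
  rel <- rspcaComponent(X, w0, solverConfig("rspca_relaxed", eta1 = 0))
  expect_equal(componentVector(soft), componentVector(ref), tolerance = 1e-12)
  expect_equal(componentVector(rel), componentVector(ref), tolerance = 1e-12)
  expect_equal(objectiveTrajectory(soft), objectiveTrajectory(ref))
  expect_equal(objectiveTrajectory(rel), objectiveTrajectory(ref))
})

test_that("over-shrinkage is flagged instead of returning a zero vector", {
  X <- matrix(c(1, 0.5), 2, 1)
  res <- rspcaComponent(X, c(1, 0), solverConfig("rspca_soft",
                                                 lambdaSoft = 10))
  expect_false(res@converged)
  expect_equal(componentVector(res), c(1, 0))  # last valid vector kept
})

test_that("RSSPCA reduces iterate-wise to PCA-L1 and relaxed RSPCA", {
  X <- trainingData(meanCenter(randomStack(24, 15, seed = 32)))
  g <- buildGridGraph(4, 6)
  w0 <- leadVector(X)

  ref <- pcaL1Component(X, w0, solverConfig("pca_l1"))
  red00 <- rsspcaComponent(X, g, w0, solverConfig("rsspca"))
  expect_equal(componentVector(red00), componentVector(ref),
               tolerance = 1e-10)
  expect_equal(objectiveTrajectory(red00), objectiveTrajectory(ref),
               tolerance = 1e-10)

  lam <- 0.4
  refR <- rspcaComponent(X, w0, solverConfig("rspca_relaxed", eta1 = lam))
  red20 <- rsspcaComponent(X, g, w0, solverConfig("rsspca", eta1 = lam))
  expect_equal(componentVector(red20), componentVector(refR),
               tolerance = 1e-10)

  # rsmpca is rsspca with eta1 pinned to zero
  redM <- rsspcaComponent(X, g, w0, solverConfig("rsmpca", eta2 = 0.5))
  redS <- rsspcaComponent(X, g, w0, solverConfig("rsspca", eta1 = 0,
                                                 eta2 = 0.5))
  expect_equal(componentVector(redM), componentVector(redS),
               tolerance = 1e-12)
})

test_that("strong smoothing drives the component into the Laplacian null space", {
  # 1x2 grid: constant direction is (1,1)/sqrt(2)
  X <- matrix(c(3, 1, 2, 2), 2)
  g <- buildGridGraph(1, 2)
  w0 <- c(2, 1) / sqrt(5)  # strictly nonzero start: zeros are absorbing at eta1 = 0
  res <- rsspcaComponent(X, g, w0, solverConfig("rsspca", eta2 = 200))
  expect_equal(componentVector(res), c(1, 1) / sqrt(2), tolerance = 1e-2)

  # brute-force oracle: maximize the penalized objective on the unit circle
  theta <- seq(0, 2 * pi, length.out = 20001)
  obj <- vapply(theta, function(t) {
    w <- c(cos(t), sin(t))
    sum(abs(crossprod(X, w))) - 200 * quadraticForm(g, w)
  }, numeric(1))
  wStar <- c(cos(theta[which.max(obj)]), sin(theta[which.max(obj)]))
  if (wStar[which.max(abs(wStar))] < 0) wStar <- -wStar
  expect_equal(wStar, c(1, 1) / sqrt(2), tolerance = 1e-2)
})

test_that("PCA-L1 trajectories ascend and scale equivariantly", {
  for (s in 1:20) {
    X <- trainingData(meanCenter(randomStack(12, 10, seed = 40 + s)))
    res <- pcaL1Component(X, leadVector(X), solverConfig("pca_l1"))
    expect_gte(min(relDiffs(objectiveTrajectory(res))), -1e-12)
  }
  X <- trainingData(meanCenter(randomStack(12, 10, seed = 77)))
  w0 <- leadVector(X)
  a <- pcaL1Component(X, w0, solverConfig("pca_l1"))
  b <- pcaL1Component(3 * X, w0, solverConfig("pca_l1"))
  expect_equal(componentVector(a), componentVector(b), tolerance = 1e-12)
  expect_equal(3 * objectiveTrajectory(a), objectiveTrajectory(b),
               tolerance = 1e-12)
})

test_that("sparsity grows with eta1 and smoothness penalty shrinks with eta2", {
  ds <- makeDataset(syntheticSpec(seed = 5, noiseSd = 0.2))
  tm <- meanCenter(ds$X)
  g <- ds$truth$graph
  w0 <- leadVector(trainingData(tm))

  zeros <- vapply(10^seq(-3, 3, by = 1), function(e1) {
    res <- rsspcaComponent(tm, g, w0, solverConfig("rsspca", eta1 = e1))
    sum(abs(componentVector(res)) < 1e-3)
  }, numeric(1))
  expect_lte(sum(diff(zeros) < 0), 1)  # monotone up to one inversion
  expect_gt(zeros[length(zeros)], zeros[1])

  smooth <- vapply(10^seq(-3, 3, by = 1), function(e2) {
    res <- rsspcaComponent(tm, g, w0, solverConfig("rsspca", eta2 = e2))
    quadraticForm(g, componentVector(res))
  }, numeric(1))
  expect_lte(sum(diff(smooth) > 0), 1)
  expect_lt(smooth[length(smooth)], smooth[1])
})
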