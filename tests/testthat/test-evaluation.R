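test_that("occlusion corrupts exactly the requested number of images", {
  X <- randomStack(20 * 20, 400, seed = 61)
  spec <- occlusionSpec(fraction = 80 / 400, minSide = 10, maxSide = 20,
                        seed = 9L)
  out <- occlude(X, 20, 20, spec)
  expect_length(out$occluded, 80)
  changed <- which(colSums(out$X != X) > 0)
  expect_equal(changed, out$occluded)

  # altered pixels carry only the two extreme intensities
  lo <- min(X); hi <- max(X)
  touched <- out$X[out$X != X]
  expect_true(all(touched %in% c(lo, hi)))

  # zero fraction: untouched
  none <- occlude(X, 20, 20, occlusionSpec(fraction = 0, seed = 1L))
  expect_identical(none$X, X)
  expect_length(none$occluded, 0)

  # deterministic under the stored seed
  out2 <- occlude(X, 20, 20, spec)
  expect_identical(out$X, out2$X)

  expect_error(occlude(X, 20, 20, occlusionSpec(minSide = 10, maxSide = 30)),
               "cannot fit")
})

test_that("reconstruction error matches the residual definition", {
  expect_equal(reconstructionError(matrix(c(1, 0), 2, 1), matrix(c(3, 4), 1)),
               4)
  X <- trainingData(meanCenter(randomStack(8, 12, seed = 62)))
  full <- basisMatrix(pcaComponents(X, 8))
  expect_lt(reconstructionError(full, t(X)), 1e-8)

  W <- randomOrthonormal(8, 3, seed = 63)
  Z <- t(X)
  brute <- mean(vapply(seq_len(nrow(Z)), function(i) {
    z <- Z[i, ]
    sqrt(sum((z - W %*% crossprod(W, z))^2))
  }, numeric(1)))
  expect_equal(reconstructionError(W, Z), brute, tolerance = 1e-12)
  expect_error(reconstructionError(W, matrix(0, 0, 8)), "at least one")
})

test_that("z-score parameters come from the training set only", {
  train <- matrix(c(1, 3, 5), 1)
  test <- matrix(c(3, 7), 1)
  zs <- zscoreFitApply(train, test)
  expect_equal(as.numeric(zs$train), c(-1, 0, 1))
  expect_equal(zs$means, 3, ignore_attr = TRUE)
  expect_equal(zs$sds, 2, ignore_attr = TRUE)  # n - 1 denominator
  expect_equal(as.numeric(zs$test), c(0, 2))

  tr <- randomStack(5, 10, seed = 64)
  zs2 <- zscoreFitApply(tr, tr)
  expect_equal(rowMeans(zs2$train), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(zs2$train, 1, sd), rep(1, 5), tolerance = 1e-12)

  cst <- rbind(rep(2, 6), 1:6)
  zs3 <- zscoreFitApply(cst, cst)
  expect_equal(zs3$train[1, ], rep(0, 6))

  expect_error(zscoreFitApply(matrix(1, 2, 1), matrix(1, 2, 1)), "two")
})

test_that("nearest-neighbour rule matches an exhaustive distance scan", {
  tr <- cbind(c(0, 0), c(10, 10))
  expect_equal(nnClassify(tr, c("A", "B"), cbind(c(1, 1))), "A")
  expect_equal(nnClassify(tr, c("A", "B"), cbind(c(10, 10))), "B")

  # ties go to the lowest training index
  trTie <- cbind(c(1, 0), c(1, 0))
  expect_equal(nnClassify(trTie, c("first", "second"), cbind(c(0, 0))),
               "first")

  set.seed(65)
  trP <- matrix(rnorm(3 * 20), 3)
  teP <- matrix(rnorm(3 * 15), 3)
  labs <- sample(letters[1:4], 20, replace = TRUE)
  pred <- nnClassify(trP, labs, teP)
  brute <- vapply(seq_len(ncol(teP)), function(j) {
    d <- colSums((trP - teP[, j])^2)
    labs[which.min(d)]
  }, character(1))
  expect_equal(pred, brute)
  expect_error(nnClassify(matrix(0, 2, 0), character(0), teP), "non-empty")
})

test_that("reconstruction experiment is monotone in r for the L2 baseline", {
  ds <- makeDataset(syntheticSpec(seed = 8, height = 8, width = 8, n = 50,
                                  nComponentsTrue = 2, noiseSd = 0.3))
  spec <- occlusionSpec(fraction = 0.2, minSide = 3, maxSide = 5, seed = 2L)
  res <- runReconstructionExperiment(ds$X, 8, 8, spec,
                                     solverConfig("pca"), rMax = 15,
                                     rRange = c(1, 10))
  curve <- perComponentCurve(res)
  expect_equal(curve$r, 1:15)
  expect_true(all(diff(curve$value) <= 1e-10))
  expect_equal(overallValue(res), mean(curve$value[1:10]))

  # rerun with the same seeds: identical
  res2 <- runReconstructionExperiment(ds$X, 8, 8, spec,
                                      solverConfig("pca"), rMax = 15,
                                      rRange = c(1, 10))
  expect_identical(perComponentCurve(res), perComponentCurve(res2))

  # error vanishes with a complete basis on clean data
  clean <- randomStack(16, 40, seed = 66)
  resFull <- runReconstructionExperiment(
    clean, 4, 4, occlusionSpec(fraction = 0, seed = 1L),
    solverConfig("pca"), rMax = 16, rRange = c(16, 16))
  expect_lt(perComponentCurve(resFull)$value[16], 1e-8)
})

test_that("recognition experiment is deterministic and relabel-invariant", {
  ds <- makeDataset(syntheticSpec(seed = 9, height = 8, width = 8, n = 48,
                                  nClasses = 3, noiseSd = 0.1))
  cfg <- solverConfig("pca")
  r1 <- runRecognitionExperiment(ds$X, ds$labels, trainPerClass = 10,
                                 repeats = 2, config = cfg, rMax = 5,
                                 rRange = c(1, 5), seed = 3L)
  r2 <- runRecognitionExperiment(ds$X, ds$labels, trainPerClass = 10,
                                 repeats = 2, config = cfg, rMax = 5,
                                 rRange = c(1, 5), seed = 3L)
  expect_identical(perComponentCurve(r1), perComponentCurve(r2))

  relabel <- c("x", "y", "z")[ds$labels]
  r3 <- runRecognitionExperiment(ds$X, relabel, trainPerClass = 10,
                                 repeats = 2, config = cfg, rMax = 5,
                                 rRange = c(1, 5), seed = 3L)
  expect_equal(perComponentCurve(r3)$value, perComponentCurve(r1)$value)

  expect_error(
    runRecognitionExperiment(ds$X, ds$labels, trainPerClass = 16,
                             repeats = 1, config = cfg, rMax = 3,
                             seed = 1L),
    "more samples")
})

test_that("parameter sweep covers the grid and finds the optimum", {
  ds <- makeDataset(syntheticSpec(seed = 10, height = 8, width = 8, n = 40))
  g <- ds$truth$graph
  spec <- occlusionSpec(fraction = 0.2, minSide = 3, maxSide = 5, seed = 4L)
  cfg <- solverConfig("rsspca")

  sw <- parameterSweep("reconstruction", lgEta1 = c(-Inf, -1),
                       lgEta2 = c(-Inf, 0), config = cfg,
                       clean = ds$X, height = 8, width = 8, spec = spec,
                       rMax = 5, rRange = c(1, 5), graph = g)
  expect_equal(nrow(sw$table), 4)
  expect_equal(sw$best$overall, min(sw$table$overall))

  # a single point equals the direct call; -Inf encodes eta = 0
  one <- parameterSweep("reconstruction", lgEta1 = -Inf, lgEta2 = -Inf,
                        config = cfg, clean = ds$X, height = 8, width = 8,
                        spec = spec, rMax = 5, rRange = c(1, 5), graph = g)
  direct <- runReconstructionExperiment(ds$X, 8, 8, spec,
                                        solverConfig("rsspca"),
                                        rMax = 5, rRange = c(1, 5), graph = g)
  expect_equal(one$results[[1]]@perR$value, perComponentCurve(direct)$value)
  expect_error(parameterSweep("reconstruction", numeric(0), 1, cfg),
               "non-empty")
})
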