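#' Construct an occlusion specification
#'
#' @param fraction fraction of images to occlude, in [0, 1].
#' @param minSide,maxSide inclusive bounds on the rectangle side lengths.
#' @param seed integer seed (NA to draw from the current RNG stream).
#' @return An [OcclusionSpec-class].
#' @export
occlusionSpec <- function(fraction = 0.2, minSide = 10L, maxSide = 20L,
                          seed = NA_integer_) {
  new("OcclusionSpec", fraction = as.numeric(fraction),
      minSide = as.integer(minSide), maxSide = as.integer(maxSide),
      noiseMode = "salt_pepper", seed = as.integer(seed))
}

#' Corrupt a random subset of images with rectangular salt-and-pepper noise
#'
#' Selects \code{round(fraction * n)} distinct images and overwrites, in each,
#' one rectangle (sides uniform in \code{[minSide, maxSide]}, position
#' uniform) pixel by pixel with the global intensity minimum or maximum of the
#' input stack, each with probability one half. This emulates training sets in
#' which a fraction of images carries gross localized corruption.
#'
#' @param images d-by-n matrix, one vectorized image per column.
#' @param height,width the image grid dimensions (d = height * width).
#' @param spec an [OcclusionSpec-class].
#' @param indexOrder vectorization order used for \code{images}.
#' @return A list with \code{X} (the corrupted matrix) and \code{occluded}
#'   (sorted integer vector of altered column indices).
#' @export
occlude <- function(images, height, width, spec,
                    indexOrder = c("column_major", "row_major")) {
  indexOrder <- match.arg(indexOrder)
  stopifnot(is(spec, "OcclusionSpec"))
  if (!is.matrix(images)) images <- as.matrix(images)
  if (nrow(images) != height * width) {
    stop("nrow(images) must equal height * width")
  }
  n <- ncol(images)
  nOcc <- round(spec@fraction * n)
  if (nOcc == 0) {
    return(list(X = images, occluded = integer(0)))
  }
  if (spec@maxSide > min(height, width)) {
    stop("occlusion rectangle cannot fit: maxSide exceeds min(height, width)")
  }
  idx <- pixelIndex(height, width, indexOrder)
  lo <- min(images)
  hi <- max(images)
  withSeed(spec@seed, {
    cols <- sort(sample.int(n, nOcc))
    for (j in cols) {
      hSide <- sample(seq(spec@minSide, spec@maxSide), 1L)
      wSide <- sample(seq(spec@minSide, spec@maxSide), 1L)
      r0 <- sample.int(height - hSide + 1L, 1L)
      c0 <- sample.int(width - wSide + 1L, 1L)
      pix <- as.vector(idx[r0:(r0 + hSide - 1L), c0:(c0 + wSide - 1L)])
      images[pix, j] <- ifelse(stats::runif(length(pix)) < 0.5, lo, hi)
    }
    list(X = images, occluded = cols)
  })
}

#' Average reconstruction error of a basis on held-out images
#'
#' For \eqn{m} mean-centered images \eqn{Z_i} (rows of \code{Z}) and a basis
#' \eqn{W}, computes \eqn{\frac{1}{m}\sum_i \|Z_i (I - W W^T)\|_F}: the mean
#' Euclidean length of the residual after projecting each image onto the span
#' of the components and back.
#'
#' @param basis a [ProjectionBasis-class] or a d-by-r numeric matrix.
#' @param Z m-by-d matrix, one mean-centered image per row.
#' @return A nonnegative scalar.
#' @export
reconstructionError <- function(basis, Z) {
  W <- if (is(basis, "ProjectionBasis")) basis@W else as.matrix(basis)
  if (!is.matrix(Z)) Z <- matrix(Z, nrow = 1)
  if (ncol(Z) != nrow(W)) {
    stop("ncol(Z) must equal the feature count of the basis")
  }
  if (nrow(Z) == 0L) stop("Z must contain at least one image")
  R <- Z - (Z %*% W) %*% t(W)
  mean(sqrt(rowSums(R^2)))
}

#' Z-score normalization fitted on training data only
#'
#' Per-feature mean and standard deviation (denominator n - 1) are computed
#' on the training matrix and applied unchanged to both sets, so the test
#' data never leak into the normalization. Constant features (sd = 0) are
#' mapped to 0, with the sd treated as 1.
#'
#' @param train d-by-nTrain matrix.
#' @param test d-by-nTest matrix (may have zero columns).
#' @return A list with \code{train}, \code{test}, \code{means}, \code{sds}.
#' @export
zscoreFitApply <- function(train, test) {
  if (!is.matrix(train)) train <- as.matrix(train)
  if (!is.matrix(test)) test <- as.matrix(test)
  if (ncol(train) < 2L) stop("need at least two training samples")
  if (nrow(test) != nrow(train)) {
    stop("train and test must have the same feature count")
  }
  mu <- rowMeans(train)
  sdv <- apply(train, 1, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = (train - mu) / sdv,
       test = (test - mu) / sdv,
       means = mu, sds = sdv)
}

#' Nearest-neighbour classification in projection space
#'
#' Assigns each test point the label of its Euclidean-nearest training point;
#' exact distance ties are broken in favour of the lowest training index.
#'
#' @param trainProj r-by-nTrain matrix of projected training points.
#' @param trainLabels vector of length nTrain.
#' @param testProj r-by-nTest matrix of projected test points.
#' @return Vector of predicted labels, length nTest.
#' @export
nnClassify <- function(trainProj, trainLabels, testProj) {
  trainProj <- as.matrix(trainProj)
  testProj <- as.matrix(testProj)
  if (ncol(trainProj) == 0L) stop("training set must be non-empty")
  if (length(trainLabels) != ncol(trainProj)) {
    stop("trainLabels must match the training columns")
  }
  tr2 <- colSums(trainProj^2)
  cross <- crossprod(trainProj, testProj)  # nTrain x nTest
  nearest <- apply(tr2 - 2 * cross, 2, which.min)
  trainLabels[nearest]
}

.newEvaluationResult <- function(metric, perR, rRange, repeats = 1L,
                                 params = numeric(0)) {
  rRange <- as.integer(rRange)
  keep <- seq(rRange[1], rRange[2])
  overall <- mean(perR$value[match(keep, perR$r)])
  new("EvaluationResult", metric = metric, perR = perR, overall = overall,
      rRange = rRange, repeats = as.integer(repeats), params = params)
}

#' Occlusion-robust reconstruction experiment
#'
#' The full reconstruction protocol: corrupt a fraction of the image stack
#' with rectangular salt-and-pepper occlusions, mean-center the polluted
#' stack and train \code{rMax} components on it, then report the average
#' reconstruction error on the clean subset (mean-centered with its own
#' mean) for every component count \eqn{r = 1 \dots rMax}, plus the mean of
#' the curve over \code{rRange}.
#'
#' @param clean d-by-n matrix of uncorrupted vectorized images.
#' @param height,width image grid dimensions.
#' @param spec an [OcclusionSpec-class].
#' @param config a [SolverConfig-class].
#' @param rMax number of components to train.
#' @param rRange averaging range (clipped to \code{rMax}).
#' @param graph [GridGraph-class]; built from height/width when needed and
#'   missing.
#' @param indexOrder vectorization order of \code{clean}.
#' @return An [EvaluationResult-class] with metric
#'   \code{"reconstruction_error"}.
#' @export
runReconstructionExperiment <- function(clean, height, width, spec, config,
                                        rMax = 30L, rRange = c(1L, 30L),
                                        graph = NULL,
                                        indexOrder = "column_major") {
  rMax <- assertScalarCount(rMax, "rMax")
  rRange <- c(max(1L, as.integer(rRange[1])),
              min(as.integer(rRange[2]), rMax))
  if (is.null(graph) && config@eta2 > 0) {
    graph <- buildGridGraph(height, width, indexOrder)
  }
  occ <- occlude(clean, height, width, spec, indexOrder)
  tm <- meanCenter(occ$X, grid = graph)
  basis <- fitComponents(tm, rMax, config, graph)
  W <- basis@W
  rRange[2] <- min(rRange[2], ncol(W))

  cleanIdx <- setdiff(seq_len(ncol(clean)), occ$occluded)
  if (length(cleanIdx) == 0L) stop("no clean images left to evaluate on")
  Zc <- clean[, cleanIdx, drop = FALSE]
  Z <- t(Zc - rowMeans(Zc))  # images as rows, centered with their own mean

  vals <- vapply(seq_len(ncol(W)), function(r) {
    reconstructionError(W[, seq_len(r), drop = FALSE], Z)
  }, numeric(1))
  perR <- data.frame(r = seq_len(ncol(W)), value = vals)
  .newEvaluationResult("reconstruction_error", perR, rRange,
                       params = c(eta1 = config@eta1, eta2 = config@eta2))
}

#' Recognition experiment: z-score, project, nearest neighbour
#'
#' For each repeat, draws a stratified split (\code{trainPerClass} images per
#' class for training, the rest for testing), z-score-normalizes with
#' training parameters, fits \code{rMax} components on the normalized
#' training matrix, and classifies the test images with a nearest-neighbour
#' rule in the r-dimensional projection space for every \eqn{r = 1 \dots
#' rMax}. Accuracies are averaged over repeats per r, then over \code{rRange}.
#' Per-repeat seeds derive from \code{seed} by fixed offsets.
#'
#' @param images d-by-n matrix of vectorized images.
#' @param labels class labels, length n.
#' @param trainPerClass training images per class (every class needs more
#'   samples than this).
#' @param repeats number of random splits (default 3).
#' @param config a [SolverConfig-class].
#' @param rMax number of components (default 30).
#' @param rRange averaging range (clipped to \code{rMax}).
#' @param graph [GridGraph-class] when \code{config@eta2 > 0}.
#' @param seed master seed for the splits.
#' @return An [EvaluationResult-class] with metric \code{"accuracy"}.
#' @export
runRecognitionExperiment <- function(images, labels, trainPerClass,
                                     repeats = 3L, config,
                                     rMax = 30L, rRange = c(1L, 30L),
                                     graph = NULL, seed = 1L) {
  rMax <- assertScalarCount(rMax, "rMax")
  repeats <- assertScalarCount(repeats, "repeats")
  rRange <- c(max(1L, as.integer(rRange[1])),
              min(as.integer(rRange[2]), rMax))
  labels <- as.vector(labels)
  if (length(labels) != ncol(images)) {
    stop("labels must have one entry per image")
  }
  counts <- table(labels)
  if (any(counts <= trainPerClass)) {
    stop("every class needs more samples than trainPerClass")
  }

  accMat <- matrix(NA_real_, nrow = rMax, ncol = repeats)
  for (rep_i in seq_len(repeats)) {
    splitIdx <- withSeed(subSeed(seed, rep_i), {
      unlist(lapply(unique(labels), function(cl) {
        sample(which(labels == cl), trainPerClass)
      }), use.names = FALSE)
    })
    testIdx <- setdiff(seq_along(labels), splitIdx)
    zs <- zscoreFitApply(images[, splitIdx, drop = FALSE],
                         images[, testIdx, drop = FALSE])
    basis <- fitComponents(zs$train, rMax, config, graph)
    W <- basis@W
    trP <- crossprod(W, zs$train)
    teP <- crossprod(W, zs$test)
    truth <- labels[testIdx]
    for (r in seq_len(ncol(W))) {
      pred <- nnClassify(trP[seq_len(r), , drop = FALSE],
                         labels[splitIdx],
                         teP[seq_len(r), , drop = FALSE])
      accMat[r, rep_i] <- mean(pred == truth)
    }
  }
  perR <- data.frame(r = seq_len(rMax), value = rowMeans(accMat))
  .newEvaluationResult("accuracy", perR, rRange, repeats = repeats,
                       params = c(eta1 = config@eta1, eta2 = config@eta2))
}

#' Parameter-grid sweep over lg(eta1) and lg(eta2)
#'
#' Runs one experiment per grid point of \code{lgEta1} x \code{lgEta2}
#' (base-10 logarithms; \code{-Inf} encodes eta = 0, i.e. the reduction
#' cases) and reports the full results table together with the optimal point:
#' the minimizer for reconstruction error, the maximizer for accuracy.
#'
#' @param experiment \code{"reconstruction"} or \code{"recognition"}.
#' @param lgEta1,lgEta2 numeric grids of base-10 exponents.
#' @param config template [SolverConfig-class]; its eta1/eta2 are overwritten
#'   at each grid point.
#' @param ... arguments forwarded to [runReconstructionExperiment()] or
#'   [runRecognitionExperiment()] (everything except \code{config}).
#' @return A list with \code{table} (data.frame: lgEta1, lgEta2, overall),
#'   \code{results} (list of [EvaluationResult-class]), and \code{best}
#'   (list: lgEta1, lgEta2, overall, index).
#' @export
parameterSweep <- function(experiment = c("reconstruction", "recognition"),
                           lgEta1, lgEta2, config, ...) {
  experiment <- match.arg(experiment)
  if (length(lgEta1) == 0L || length(lgEta2) == 0L) {
    stop("parameter grids must be non-empty")
  }
  grid <- expand.grid(lgEta1 = lgEta1, lgEta2 = lgEta2,
                      KEEP.OUT.ATTRS = FALSE)
  runner <- if (experiment == "reconstruction") {
    function(cfg, ...) runReconstructionExperiment(config = cfg, ...)
  } else {
    function(cfg, ...) runRecognitionExperiment(config = cfg, ...)
  }
  results <- vector("list", nrow(grid))
  overall <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- config
    cfg@eta1 <- if (is.finite(grid$lgEta1[i])) 10^grid$lgEta1[i] else 0
    cfg@eta2 <- if (is.finite(grid$lgEta2[i])) 10^grid$lgEta2[i] else 0
    results[[i]] <- runner(cfg, ...)
    overall[i] <- results[[i]]@overall
  }
  tab <- cbind(grid, overall = overall)
  bestIdx <- if (experiment == "reconstruction") {
    which.min(overall)
  } else {
    which.max(overall)
  }
  list(table = tab, results = results,
       best = list(lgEta1 = grid$lgEta1[bestIdx],
                   lgEta2 = grid$lgEta2[bestIdx],
                   overall = overall[bestIdx], index = bestIdx))
}
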