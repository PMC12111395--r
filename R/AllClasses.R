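#' @import methods
#' @importFrom Matrix Diagonal sparseMatrix rowSums diag t isSymmetric
NULL

#' Pixel-lattice graph of an image grid
#'
#' Encodes the 4-connected neighbourhood structure of an \code{height} by
#' \code{width} pixel grid as sparse adjacency, degree and (combinatorial)
#' Laplacian matrices, together with the pixel-to-vector index convention used
#' when images are flattened. Two pixels are adjacent exactly when their
#' Euclidean distance on the lattice is 1, so the Laplacian quadratic form
#' \eqn{w^T L w = \frac{1}{2}\sum_{ij} A_{ij} (w_i - w_j)^2} penalises
#' differences between weights of neighbouring pixels.
#'
#' @slot height,width grid dimensions in pixels.
#' @slot d number of pixels, \code{height * width}.
#' @slot adjacency sparse symmetric 0/1 matrix \eqn{A} (\code{d} by \code{d}).
#' @slot degree sparse diagonal matrix \eqn{D} of vertex degrees.
#' @slot laplacian sparse symmetric matrix \eqn{L = D - A}.
#' @slot indexOrder \code{"column_major"} or \code{"row_major"}: how pixel
#'   (row, col) maps to a vector index. The same order must be used when
#'   vectorizing images.
#'
#' @seealso [buildGridGraph()], [quadraticForm()]
#' @export
setClass("GridGraph",
  representation(
    height = "integer",
    width = "integer",
    d = "integer",
    adjacency = "Matrix",
    degree = "Matrix",
    laplacian = "Matrix",
    indexOrder = "character"
  )
)

setValidity("GridGraph", function(object) {
  msg <- character()
  if (object@height < 1L || object@width < 1L) {
    msg <- c(msg, "height and width must be positive")
  }
  if (object@d != object@height * object@width) {
    msg <- c(msg, "d must equal height * width")
  }
  if (!all(dim(object@adjacency) == object@d) ||
      !all(dim(object@laplacian) == object@d)) {
    msg <- c(msg, "adjacency and laplacian must be d x d")
  }
  if (!object@indexOrder %in% c("column_major", "row_major")) {
    msg <- c(msg, "indexOrder must be 'column_major' or 'row_major'")
  }
  if (length(msg)) msg else TRUE
})

#' Vectorized image stack with centering metadata
#'
#' A \code{d} by \code{n} matrix holding one vectorized image per column,
#' together with the per-feature mean that was subtracted (the zero vector when
#' the stack is not centered) and, optionally, the [GridGraph-class] describing
#' the pixel lattice the rows live on.
#'
#' @slot X numeric matrix, features by samples.
#' @slot center numeric vector of length \code{d}, the subtracted row means.
#' @slot grid a [GridGraph-class] consistent with \code{nrow(X)}, or NULL.
#'
#' @seealso [meanCenter()]
#' @export
setClass("TrainingMatrix",
  representation(
    X = "matrix",
    center = "numeric",
    grid = "ANY"
  )
)

setValidity("TrainingMatrix", function(object) {
  msg <- character()
  if (nrow(object@X) < 1L || ncol(object@X) < 1L) {
    msg <- c(msg, "X must have at least one row and one column")
  }
  if (length(object@center) != nrow(object@X)) {
    msg <- c(msg, "center must have length nrow(X)")
  }
  if (!is.null(object@grid)) {
    if (!is(object@grid, "GridGraph")) {
      msg <- c(msg, "grid must be a GridGraph or NULL")
    } else if (object@grid@d != nrow(object@X)) {
      msg <- c(msg, "grid dimension does not match nrow(X)")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Solver configuration
#'
#' Bundles the algorithm variant and its hyperparameters. \code{eta1} weighs
#' the sparsity (L1) constraint and \code{eta2} the Laplacian smoothness
#' constraint relative to the unit-norm constraint; both are zero for the
#' unconstrained variants. \code{lambdaSoft} is the shrinkage threshold of the
#' soft-thresholding RSPCA update and is ignored by every other variant.
#'
#' @slot variant one of \code{"pca"}, \code{"pca_l1"}, \code{"rspca_soft"},
#'   \code{"rspca_relaxed"}, \code{"rsmpca"}, \code{"rsspca"}.
#' @slot eta1,eta2 nonnegative sparsity / smoothness weights.
#' @slot lambdaSoft nonnegative soft-threshold level (rspca_soft only).
#' @slot tol positive relative-change convergence tolerance (default 1e-4).
#' @slot maxIter iteration cap per component (default 100).
#' @slot seed integer seed consumed by stochastic callers (NA for none).
#'
#' @seealso [solverConfig()], [fitComponents()]
#' @export
setClass("SolverConfig",
  representation(
    variant = "character",
    eta1 = "numeric",
    eta2 = "numeric",
    lambdaSoft = "numeric",
    tol = "numeric",
    maxIter = "integer",
    seed = "integer"
  )
)

.solverVariants <- c("pca", "pca_l1", "rspca_soft", "rspca_relaxed",
                     "rsmpca", "rsspca")

setValidity("SolverConfig", function(object) {
  msg <- character()
  if (!object@variant %in% .solverVariants) {
    msg <- c(msg, paste0("variant must be one of: ",
                         paste(.solverVariants, collapse = ", ")))
  }
  if (object@eta1 < 0 || object@eta2 < 0 || object@lambdaSoft < 0) {
    msg <- c(msg, "eta1, eta2 and lambdaSoft must be nonnegative")
  }
  if (object@tol <= 0) msg <- c(msg, "tol must be positive")
  if (object@maxIter < 1L) msg <- c(msg, "maxIter must be at least 1")
  if (length(msg)) msg else TRUE
})

#' Result of a single-component solve
#'
#' Holds one unit-norm projection vector together with the trajectory of the
#' L1 objective \eqn{f(k) = \|X^T w^{(k)}\|_1} recorded from the initial
#' vector onwards, the number of update steps taken, and convergence flags.
#'
#' @slot w unit-norm numeric vector.
#' @slot objective numeric vector, \eqn{f(k)} for \eqn{k = 0, 1, \dots}.
#' @slot iterations number of completed update steps.
#' @slot converged TRUE when the relative objective change fell to the
#'   tolerance before the iteration cap.
#' @slot ridgeFallback TRUE when a singular linear system forced the ridge
#'   regularized solve.
#'
#' @export
setClass("ComponentResult",
  representation(
    w = "numeric",
    objective = "numeric",
    iterations = "integer",
    converged = "logical",
    ridgeFallback = "logical"
  )
)

setValidity("ComponentResult", function(object) {
  msg <- character()
  nrm <- sqrt(sum(object@w^2))
  if (abs(nrm - 1) > 1e-8) msg <- c(msg, "w must have unit L2 norm")
  if (any(object@objective < 0)) msg <- c(msg, "objective values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Stack of extracted projection vectors
#'
#' The \code{d} by \code{r} matrix of unit-norm components found by the
#' deflation loop, with per-component diagnostics and the configuration that
#' produced them.
#'
#' @slot W numeric matrix, one unit-norm component per column.
#' @slot r number of components.
#' @slot perComponent list of [ComponentResult-class] objects.
#' @slot config the [SolverConfig-class] used.
#'
#' @seealso [fitComponents()], [pcaComponents()]
#' @export
setClass("ProjectionBasis",
  representation(
    W = "matrix",
    r = "integer",
    perComponent = "list",
    config = "SolverConfig"
  )
)

setValidity("ProjectionBasis", function(object) {
  msg <- character()
  if (ncol(object@W) != object@r) msg <- c(msg, "ncol(W) must equal r")
  if (object@r > nrow(object@W)) msg <- c(msg, "r must not exceed d")
  nrms <- sqrt(colSums(object@W^2))
  if (object@r > 0 && any(abs(nrms - 1) > 1e-8)) {
    msg <- c(msg, "every column of W must have unit L2 norm")
  }
  if (length(msg)) msg else TRUE
})

#' Rectangular salt-and-pepper occlusion settings
#'
#' Describes how a fraction of images in a stack is corrupted: each selected
#' image receives one rectangle, with side lengths drawn uniformly from
#' \code{[minSide, maxSide]} and a uniform position, whose pixels are
#' overwritten with the global intensity minimum or maximum (fair coin per
#' pixel).
#'
#' @slot fraction fraction of images to occlude, in [0, 1].
#' @slot minSide,maxSide integer bounds on rectangle side lengths.
#' @slot noiseMode only \code{"salt_pepper"}.
#' @slot seed integer seed (NA to use the current RNG state).
#'
#' @seealso [occlude()]
#' @export
setClass("OcclusionSpec",
  representation(
    fraction = "numeric",
    minSide = "integer",
    maxSide = "integer",
    noiseMode = "character",
    seed = "integer"
  )
)

setValidity("OcclusionSpec", function(object) {
  msg <- character()
  if (object@fraction < 0 || object@fraction > 1) {
    msg <- c(msg, "fraction must be in [0, 1]")
  }
  if (object@minSide < 1L) msg <- c(msg, "minSide must be at least 1")
  if (object@maxSide < object@minSide) {
    msg <- c(msg, "maxSide must be >= minSide")
  }
  if (!identical(object@noiseMode, "salt_pepper")) {
    msg <- c(msg, "noiseMode must be 'salt_pepper'")
  }
  if (length(msg)) msg else TRUE
})

#' Metric-versus-components evaluation curve
#'
#' A reconstruction-error or classification-accuracy curve indexed by the
#' number of components \code{r}, with the overall value defined as the
#' arithmetic mean over the averaging range \code{rRange}.
#'
#' @slot metric \code{"reconstruction_error"} or \code{"accuracy"}.
#' @slot perR data.frame with columns \code{r} and \code{value}.
#' @slot overall mean of \code{value} over \code{rRange}.
#' @slot rRange integer pair, inclusive averaging range.
#' @slot repeats number of random repetitions averaged (1 when none).
#' @slot params named numeric vector (eta1, eta2) when applicable.
#'
#' @export
setClass("EvaluationResult",
  representation(
    metric = "character",
    perR = "data.frame",
    overall = "numeric",
    rRange = "integer",
    repeats = "integer",
    params = "numeric"
  )
)

setValidity("EvaluationResult", function(object) {
  msg <- character()
  if (!object@metric %in% c("reconstruction_error", "accuracy")) {
    msg <- c(msg, "metric must be 'reconstruction_error' or 'accuracy'")
  }
  if (!all(c("r", "value") %in% names(object@perR))) {
    msg <- c(msg, "perR must have columns r and value")
  } else {
    rr <- object@rRange
    covered <- object@perR$r
    want <- seq(rr[1], rr[2])
    if (!all(want %in% covered)) {
      msg <- c(msg, "perR must cover every r in rRange")
    } else {
      m <- mean(object@perR$value[match(want, covered)])
      if (abs(m - object@overall) > 1e-12 * max(1, abs(m))) {
        msg <- c(msg, "overall must equal the mean of values over rRange")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Synthetic image-stack generator settings
#'
#' Parameters of the simulated study: a stack of \code{n} images on an
#' \code{height} by \code{width} grid generated from planted components that
#' are simultaneously sparse (a fraction \code{sparsity} of exactly-zero
#' pixels) and spatially smooth (Gaussian-profile blobs of radius
#' \code{smoothScale}), plus Gaussian background noise, an optional fraction
#' of images corrupted by rectangular salt-and-pepper occlusions, and optional
#' class structure whose discriminative patterns are themselves sparse-smooth.
#'
#' @slot height,width grid dimensions (each at least 4).
#' @slot n number of images.
#' @slot nComponentsTrue number of planted components.
#' @slot sparsity fraction of zero pixels in each true component, in [0, 1].
#' @slot smoothScale blob radius in pixels.
#' @slot noiseSd standard deviation of the additive Gaussian noise.
#' @slot outlierFraction fraction of images occluded, in [0, 1].
#' @slot nClasses number of classes (0 for unlabelled data).
#' @slot seed master seed; all randomness derives from it.
#'
#' @seealso [syntheticSpec()], [makeDataset()]
#' @export
setClass("SyntheticSpec",
  representation(
    height = "integer",
    width = "integer",
    n = "integer",
    nComponentsTrue = "integer",
    sparsity = "numeric",
    smoothScale = "numeric",
    noiseSd = "numeric",
    outlierFraction = "numeric",
    nClasses = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@height < 4L || object@width < 4L) {
    msg <- c(msg, "height and width must be at least 4")
  }
  if (object@n < object@nComponentsTrue) {
    msg <- c(msg, "n must be at least nComponentsTrue")
  }
  if (object@sparsity < 0 || object@sparsity > 1 ||
      object@outlierFraction < 0 || object@outlierFraction > 1) {
    msg <- c(msg, "sparsity and outlierFraction must be in [0, 1]")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be nonnegative")
  if (object@nComponentsTrue < 1L) {
    msg <- c(msg, "nComponentsTrue must be at least 1")
  }
  if (length(msg)) msg else TRUE
})
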