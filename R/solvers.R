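#' Mean-center an image stack
#'
#' Subtracts the per-feature (row) mean from a features-by-samples matrix and
#' records the subtracted mean so that new data can be centered consistently.
#'
#' @param X numeric matrix (d features by n samples) or a
#'   [TrainingMatrix-class] (re-centered from its raw values).
#' @param grid optional [GridGraph-class] attached to the result.
#' @return A [TrainingMatrix-class] whose rows have zero mean.
#' @export
meanCenter <- function(X, grid = NULL) {
  if (is(X, "TrainingMatrix")) {
    if (is.null(grid)) grid <- X@grid
    X <- X@X
  }
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) == 0L || ncol(X) == 0L) stop("X must be non-empty")
  ctr <- rowMeans(X)
  new("TrainingMatrix", X = X - ctr, center = ctr, grid = grid)
}

#' L1 projection objective
#'
#' The quantity every iterative solver in this package maximizes:
#' \eqn{\|X^T w\|_1 = \sum_i |x_i^T w|}, the summed absolute projections of
#' the samples onto \code{w}. Using the L1 rather than the squared L2 norm is
#' what makes the extracted components robust to outlying images.
#'
#' @param X a [TrainingMatrix-class] or a d-by-n numeric matrix.
#' @param w numeric vector of length d.
#' @return A nonnegative scalar.
#' @export
l1Objective <- function(X, w) {
  X <- asTrainingMatrix(X)@X
  if (length(w) != nrow(X)) {
    stop("length(w) must equal the feature count of X")
  }
  sum(abs(crossprod(X, w)))
}

#' Elementwise sign with sign(0) = 0
#'
#' @param x numeric vector.
#' @return Vector in \{-1, 0, 1\}.
#' @export
signVec <- function(x) sign(x)

#' Soft-thresholding (shrinkage) operator
#'
#' \eqn{soft(v, \lambda)_i = sign(v_i) \max(|v_i| - \lambda, 0)}: entries with
#' magnitude at most \code{lam} are zeroed, the rest shrink toward zero.
#'
#' @param v numeric vector.
#' @param lam nonnegative scalar threshold.
#' @return Shrunken vector of the same length.
#' @export
softThreshold <- function(v, lam) {
  if (length(lam) != 1L || is.na(lam) || lam < 0) {
    stop("lam must be a nonnegative scalar")
  }
  sign(v) * pmax(abs(v) - lam, 0)
}

#' Construct a solver configuration
#'
#' @param variant algorithm variant; see [SolverConfig-class].
#' @param eta1 nonnegative sparsity weight (also used as the relaxed-update
#'   shrinkage level of \code{rspca_relaxed}).
#' @param eta2 nonnegative smoothness weight.
#' @param lambdaSoft soft-threshold level for \code{rspca_soft}.
#' @param tol relative objective-change tolerance.
#' @param maxIter iteration cap per component.
#' @param seed integer seed for stochastic callers (NA for none).
#' @return A [SolverConfig-class].
#' @export
solverConfig <- function(variant = "rsspca", eta1 = 0, eta2 = 0,
                         lambdaSoft = 0, tol = 1e-4, maxIter = 100L,
                         seed = NA_integer_) {
  new("SolverConfig", variant = variant, eta1 = as.numeric(eta1),
      eta2 = as.numeric(eta2), lambdaSoft = as.numeric(lambdaSoft),
      tol = as.numeric(tol), maxIter = as.integer(maxIter),
      seed = as.integer(seed))
}

# Shared MM iteration. `update` maps (w, v) to the unnormalized next vector u
# (possibly with attribute "ridge" = TRUE when a ridge fallback fired);
# returning NULL signals a degenerate step (u = 0 or v = 0), in which case the
# last valid w is kept and the component is flagged non-converged.
mmIterate <- function(X, w0, tol, maxIter, update) {
  w <- w0
  f <- sum(abs(crossprod(X, w)))
  traj <- f
  ridge <- FALSE
  k <- 0L
  converged <- FALSE
  while (k < maxIter) {
    v <- as.numeric(X %*% sign(as.numeric(crossprod(X, w))))
    u <- update(w, v)
    if (is.null(u) || !all(is.finite(u)) || all(u == 0)) break
    if (isTRUE(attr(u, "ridge"))) ridge <- TRUE
    wNew <- as.numeric(u) / sqrt(sum(u^2))
    fNew <- sum(abs(crossprod(X, wNew)))
    delta <- abs(fNew - f) / max(f, 1e-300)
    w <- wNew
    f <- fNew
    traj <- c(traj, fNew)
    k <- k + 1L
    if (delta <= tol) {
      converged <- TRUE
      break
    }
  }
  new("ComponentResult", w = w, objective = traj, iterations = k,
      converged = converged, ridgeFallback = ridge)
}

#' Single component by L1-norm power iteration (PCA-L1)
#'
#' Iterates \eqn{v = X\,sign(X^T w)}, \eqn{w \leftarrow v/\|v\|_2} until the
#' relative change of \eqn{\|X^T w\|_1} drops to \code{tol}. Each step is an
#' exact maximization of the linear minorizer of the objective on the unit
#' sphere, so the objective never decreases; the fixed point reached depends
#' on the initialization (local optimum).
#'
#' @param X a [TrainingMatrix-class] or d-by-n matrix (assumed centered).
#' @param w0 unit-norm starting vector.
#' @param config a [SolverConfig-class]; only \code{tol}/\code{maxIter} used.
#' @return A [ComponentResult-class].
#' @export
pcaL1Component <- function(X, w0, config = solverConfig("pca_l1")) {
  X <- asTrainingMatrix(X)@X
  checkStart(X, w0)
  mmIterate(X, w0, config@tol, config@maxIter, function(w, v) {
    if (all(v == 0)) NULL else v
  })
}

#' Single robust sparse component (RSPCA), both published update rules
#'
#' Both variants start each step from \eqn{v = X\,sign(X^T w)} and then apply
#' a sparsifying correction before renormalizing:
#' \describe{
#'   \item{\code{rspca_soft}}{\eqn{u = soft(v, \lambda)} with
#'     \eqn{\lambda = } \code{config@lambdaSoft} (objective relaxed only).}
#'   \item{\code{rspca_relaxed}}{\eqn{u_i = v_i |w_i| / (\lambda + |w_i|)}
#'     with \eqn{\lambda = } \code{config@eta1} (objective and constraint both
#'     relaxed). At \eqn{\lambda = 0} both reduce to PCA-L1.}
#' }
#'
#' @inheritParams pcaL1Component
#' @param config a [SolverConfig-class] with variant \code{"rspca_soft"} or
#'   \code{"rspca_relaxed"}.
#' @return A [ComponentResult-class]; flagged non-converged when shrinkage
#'   annihilates the update (over-shrunk), with the last valid vector kept.
#' @export
rspcaComponent <- function(X, w0, config) {
  X <- asTrainingMatrix(X)@X
  checkStart(X, w0)
  if (!config@variant %in% c("rspca_soft", "rspca_relaxed")) {
    stop("config@variant must be 'rspca_soft' or 'rspca_relaxed'")
  }
  if (config@variant == "rspca_soft") {
    lam <- config@lambdaSoft
    upd <- function(w, v) {
      u <- sign(v) * pmax(abs(v) - lam, 0)
      if (all(u == 0)) NULL else u
    }
  } else {
    lam <- config@eta1
    upd <- function(w, v) {
      aw <- abs(w)
      u <- v * aw / (lam + aw)
      if (all(u == 0)) NULL else u
    }
  }
  mmIterate(X, w0, config@tol, config@maxIter, upd)
}

#' Single robust sparse smooth component (RSSPCA)
#'
#' The core update of the package. With \eqn{U = diag(|w|)},
#' \eqn{v = X\,sign(X^T w)} and grid Laplacian \eqn{L}, each MM step solves
#' the (generally nonsymmetric) linear system
#' \deqn{(U + \eta_1 I + \eta_2 U L)\, u = U v,}
#' then renormalizes \eqn{w \leftarrow u/\|u\|_2}. This form of the update
#' tolerates exact zeros in \eqn{w}: it is the division-free rewrite of
#' \eqn{(I + \eta_1 U^{-1} + \eta_2 L)^{-1} v}. Setting \eqn{\eta_1 = 0}
#' gives the robust smooth variant (RSMPCA), \eqn{\eta_2 = 0} recovers the
#' relaxed RSPCA update with \eqn{\lambda = \eta_1}, and both zero recovers
#' PCA-L1.
#'
#' If the system is numerically singular (possible at \eqn{\eta_1 = 0} when
#' \eqn{w} has zero entries) a ridge \eqn{\epsilon I} with
#' \eqn{\epsilon = 10^{-12}} times the mean absolute diagonal is added and
#' the fallback is recorded in the result.
#'
#' @inheritParams pcaL1Component
#' @param graph a [GridGraph-class] with \code{graph@d == nrow(X)}; may be
#'   NULL when \code{config@eta2 == 0}.
#' @param config a [SolverConfig-class] supplying \code{eta1}, \code{eta2},
#'   \code{tol}, \code{maxIter}.
#' @return A [ComponentResult-class].
#' @export
rsspcaComponent <- function(X, graph, w0, config) {
  X <- asTrainingMatrix(X)@X
  checkStart(X, w0)
  d <- nrow(X)
  eta1 <- if (config@variant == "rsmpca") 0 else config@eta1
  eta2 <- config@eta2
  L <- NULL
  if (eta2 > 0) {
    if (is.null(graph)) stop("a GridGraph is required when eta2 > 0")
    stopifnot(is(graph, "GridGraph"))
    if (graph@d != d) stop("graph dimension does not match nrow(X)")
    L <- graph@laplacian
  }
  I <- Matrix::Diagonal(d)
  upd <- function(w, v) {
    aw <- abs(w)
    if (is.null(L)) {
      # diagonal system: closed form
      u <- (aw * v) / (aw + eta1)
      u[aw + eta1 == 0] <- 0
      if (all(u == 0)) return(NULL)
      return(u)
    }
    U <- Matrix::Diagonal(d, aw)
    M <- U + eta1 * I + eta2 * (U %*% L)
    rhs <- aw * v
    u <- tryCatch(as.numeric(Matrix::solve(M, rhs)),
                  error = function(e) NULL)
    if (is.null(u) || !all(is.finite(u))) {
      eps <- 1e-12 * mean(abs(Matrix::diag(M)))
      u <- tryCatch(as.numeric(Matrix::solve(M + eps * I, rhs)),
                    error = function(e) NULL)
      if (is.null(u)) return(NULL)
      attr(u, "ridge") <- TRUE
    }
    if (all(u == 0)) return(NULL)
    u
  }
  mmIterate(X, w0, config@tol, config@maxIter, upd)
}

checkStart <- function(X, w0) {
  if (length(w0) != nrow(X)) {
    stop("w0 must have length nrow(X)")
  }
  if (abs(sqrt(sum(w0^2)) - 1) > 1e-8) {
    stop("w0 must have unit L2 norm")
  }
  invisible(TRUE)
}

#' Classical L2 principal components (eigendecomposition baseline)
#'
#' Top-\code{r} eigenvectors of \eqn{X X^T} (equivalently the left singular
#' vectors of \eqn{X}), orthonormal and ordered by decreasing eigenvalue.
#' Columns are sign-fixed so the largest-magnitude entry is positive; within
#' a degenerate eigenvalue subspace the basis is not unique and the returned
#' vectors are whatever the underlying SVD produces under that convention.
#'
#' @param X a [TrainingMatrix-class] or d-by-n matrix (center it first for
#'   covariance eigenvectors).
#' @param r number of components, between 1 and \code{min(d, n)}.
#' @return A [ProjectionBasis-class] with orthonormal columns.
#' @export
pcaComponents <- function(X, r) {
  X <- asTrainingMatrix(X)@X
  r <- assertScalarCount(r, "r")
  if (r > min(dim(X))) {
    stop("r must be at most min(nrow(X), ncol(X))")
  }
  sv <- svd(X, nu = r, nv = 0)
  W <- signFix(sv$u[, seq_len(r), drop = FALSE])
  per <- lapply(seq_len(r), function(j) {
    w <- W[, j]
    new("ComponentResult", w = w,
        objective = sum(abs(crossprod(X, w))),
        iterations = 0L, converged = TRUE, ridgeFallback = FALSE)
  })
  new("ProjectionBasis", W = W, r = r, perComponent = per,
      config = solverConfig("pca"))
}
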