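#' Extract multiple components by deflation
#'
#' The outer loop shared by every variant: for \eqn{i = 1, \dots, r} the
#' starting vector is the leading L2 eigenvector of the current (deflated)
#' matrix, the variant's single-component solver is run to convergence, the
#' component is sign-fixed and appended, and the data are deflated with the
#' full stack found so far, \eqn{X \leftarrow (I - W W^T) X}. For the L1
#' variants \eqn{W} is not exactly orthogonal, and the deflation is applied
#' as written without re-orthogonalization.
#'
#' @param X a [TrainingMatrix-class] or d-by-n matrix. Center it first
#'   ([meanCenter()]) unless the data are already centered/normalized.
#' @param r number of components to extract (at most d).
#' @param config a [SolverConfig-class] selecting the variant and its
#'   parameters.
#' @param graph a [GridGraph-class]; required when \code{config@eta2 > 0}
#'   (taken from \code{X@grid} when present).
#' @return A [ProjectionBasis-class]. If the deflated matrix becomes
#'   numerically zero before \code{r} components are found, fewer components
#'   are returned with a warning.
#'
#' @examples
#' set.seed(1)
#' g <- buildGridGraph(8, 8)
#' X <- matrix(rnorm(64 * 30), 64, 30)
#' tm <- meanCenter(X, grid = g)
#' fit <- fitComponents(tm, r = 3, solverConfig("rsspca", eta1 = 0.1, eta2 = 1))
#' crossprod(basisMatrix(fit))  # near-orthogonal stack
#' @export
fitComponents <- function(X, r, config, graph = NULL) {
  tm <- asTrainingMatrix(X)
  if (is.null(graph) && !is.null(tm@grid)) graph <- tm@grid
  Xd <- tm@X
  d <- nrow(Xd)
  r <- assertScalarCount(r, "r")
  if (r > d) stop("r must be at most the feature count d")
  if (config@eta2 > 0 && is.null(graph) &&
      config@variant %in% c("rsmpca", "rsspca")) {
    stop("a GridGraph is required when eta2 > 0")
  }

  scale0 <- sqrt(sum(Xd^2))
  W <- matrix(numeric(0), nrow = d, ncol = 0)
  per <- vector("list", 0)
  for (i in seq_len(r)) {
    if (sqrt(sum(Xd^2)) <= 1e-12 * max(scale0, 1)) {
      warning(sprintf(
        "deflated matrix numerically zero after %d components; returning %d",
        i - 1L, i - 1L))
      break
    }
    w0 <- as.numeric(svd(Xd, nu = 1, nv = 0)$u[, 1])
    res <- switch(config@variant,
      pca = new("ComponentResult", w = w0,
                objective = sum(abs(crossprod(Xd, w0))),
                iterations = 0L, converged = TRUE, ridgeFallback = FALSE),
      pca_l1 = pcaL1Component(Xd, w0, config),
      rspca_soft = rspcaComponent(Xd, w0, config),
      rspca_relaxed = rspcaComponent(Xd, w0, config),
      rsmpca = rsspcaComponent(Xd, graph, w0, config),
      rsspca = rsspcaComponent(Xd, graph, w0, config),
      stop("unknown variant: ", config@variant)
    )
    w <- signFix(res@w)
    res@w <- w
    W <- cbind(W, w)
    per[[i]] <- res
    Xd <- Xd - W %*% crossprod(W, Xd)
  }
  colnames(W) <- NULL
  new("ProjectionBasis", W = W, r = ncol(W), perComponent = per,
      config = config)
}
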