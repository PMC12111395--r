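#' Accessors for rsspca classes
#'
#' Small accessor generics so that user code never touches slots directly:
#' \code{adjacency}, \code{degreeMatrix} and \code{laplacian} return the three
#' sparse matrices of a [GridGraph-class]; \code{gridDim} its (height, width);
#' \code{trainingData} and \code{centerVector} the matrix and centering vector
#' of a [TrainingMatrix-class]; \code{basisMatrix} and \code{nComponents} the
#' component stack of a [ProjectionBasis-class]; \code{componentVector} and
#' \code{objectiveTrajectory} the vector and objective path of a
#' [ComponentResult-class]; \code{perComponentCurve} and \code{overallValue}
#' the curve and its average from an [EvaluationResult-class].
#'
#' @param x the object to access.
#' @return The slot value described above.
#' @name accessors
#' @aliases adjacency degreeMatrix laplacian gridDim trainingData
#'   centerVector basisMatrix nComponents componentVector
#'   objectiveTrajectory perComponentCurve overallValue
NULL

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("degreeMatrix", function(x) standardGeneric("degreeMatrix"))
#' @rdname accessors
#' @export
setGeneric("laplacian", function(x) standardGeneric("laplacian"))
#' @rdname accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))
#' @rdname accessors
#' @export
setGeneric("trainingData", function(x) standardGeneric("trainingData"))
#' @rdname accessors
#' @export
setGeneric("centerVector", function(x) standardGeneric("centerVector"))
#' @rdname accessors
#' @export
setGeneric("basisMatrix", function(x) standardGeneric("basisMatrix"))
#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setGeneric("componentVector", function(x) standardGeneric("componentVector"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrajectory",
           function(x) standardGeneric("objectiveTrajectory"))
#' @rdname accessors
#' @export
setGeneric("perComponentCurve",
           function(x) standardGeneric("perComponentCurve"))
#' @rdname accessors
#' @export
setGeneric("overallValue", function(x) standardGeneric("overallValue"))

#' @rdname accessors
setMethod("adjacency", "GridGraph", function(x) x@adjacency)
#' @rdname accessors
setMethod("degreeMatrix", "GridGraph", function(x) x@degree)
#' @rdname accessors
setMethod("laplacian", "GridGraph", function(x) x@laplacian)
#' @rdname accessors
setMethod("gridDim", "GridGraph", function(x) {
  c(height = x@height, width = x@width)
})
#' @rdname accessors
setMethod("trainingData", "TrainingMatrix", function(x) x@X)
#' @rdname accessors
setMethod("centerVector", "TrainingMatrix", function(x) x@center)
#' @rdname accessors
setMethod("basisMatrix", "ProjectionBasis", function(x) x@W)
#' @rdname accessors
setMethod("nComponents", "ProjectionBasis", function(x) x@r)
#' @rdname accessors
setMethod("componentVector", "ComponentResult", function(x) x@w)
#' @rdname accessors
setMethod("objectiveTrajectory", "ComponentResult", function(x) x@objective)
#' @rdname accessors
setMethod("perComponentCurve", "EvaluationResult", function(x) x@perR)
#' @rdname accessors
setMethod("overallValue", "EvaluationResult", function(x) x@overall)

setMethod("show", "GridGraph", function(object) {
  cat(sprintf("GridGraph: %d x %d pixel lattice (d = %d), 4-connected, %s\n",
              object@height, object@width, object@d, object@indexOrder))
  cat(sprintf("  edges: %d; Laplacian stored sparse (%s)\n",
              as.integer(sum(object@adjacency) / 2),
              class(object@laplacian)[1]))
  invisible(object)
})

setMethod("show", "TrainingMatrix", function(object) {
  centered <- any(object@center != 0)
  cat(sprintf("TrainingMatrix: %d features x %d samples (%scentered%s)\n",
              nrow(object@X), ncol(object@X),
              if (centered) "" else "not ",
              if (is.null(object@grid)) "" else ", with grid"))
  invisible(object)
})

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf(
    "SolverConfig: variant = %s, eta1 = %g, eta2 = %g, tol = %g, maxIter = %d\n",
    object@variant, object@eta1, object@eta2, object@tol, object@maxIter))
  if (object@variant == "rspca_soft") {
    cat(sprintf("  lambdaSoft = %g\n", object@lambdaSoft))
  }
  invisible(object)
})

setMethod("show", "ComponentResult", function(object) {
  cat(sprintf(
    "ComponentResult: d = %d, %d iterations, %s, final objective %.6g\n",
    length(object@w), object@iterations,
    if (object@converged) "converged" else "NOT converged",
    object@objective[length(object@objective)]))
  invisible(object)
})

setMethod("show", "ProjectionBasis", function(object) {
  cat(sprintf("ProjectionBasis: %d components in %d dimensions (%s)\n",
              object@r, nrow(object@W), object@config@variant))
  invisible(object)
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(
    "EvaluationResult: %s, r in [%d, %d], overall %.6g (%d repeat%s)\n",
    object@metric, object@rRange[1], object@rRange[2], object@overall,
    object@repeats, if (object@repeats == 1) "" else "s"))
  invisible(object)
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d x %d grid, n = %d, k = %d, sparsity %.2f, noise sd %.3g\n",
    object@height, object@width, object@n, object@nComponentsTrue,
    object@sparsity, object@noiseSd))
  if (object@outlierFraction > 0) {
    cat(sprintf("  occluded fraction: %.2f\n", object@outlierFraction))
  }
  if (object@nClasses > 0) {
    cat(sprintf("  classes: %d\n", object@nClasses))
  }
  invisible(object)
})
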