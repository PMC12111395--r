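#' Build the 4-connected pixel-lattice graph of an image grid
#'
#' Constructs the adjacency matrix \eqn{A} (1 exactly when two pixels are at
#' Euclidean distance 1 on the 2-D plane, i.e. horizontal or vertical
#' neighbours; diagonal neighbours are excluded), the diagonal degree matrix
#' \eqn{D = diag(1^T A)}, and the combinatorial Laplacian \eqn{L = D - A} for
#' an \code{height} by \code{width} grid. All three are stored sparse; the
#' contract is on values, not representation.
#'
#' The \code{indexOrder} fixes how pixel (row, col) maps to a vector index
#' (\code{column_major}: index = (col-1)*height + row, R's native order). The
#' same order must be used when vectorizing images so that graph indices and
#' pixel values line up.
#'
#' @param height,width positive integers, the grid dimensions in pixels.
#' @param indexOrder \code{"column_major"} (default) or \code{"row_major"}.
#' @return A [GridGraph-class].
#'
#' @examples
#' g <- buildGridGraph(6, 6)
#' table(Matrix::diag(degreeMatrix(g)))  # corners 2, edges 3, interior 4
#' @export
buildGridGraph <- function(height, width,
                           indexOrder = c("column_major", "row_major")) {
  indexOrder <- match.arg(indexOrder)
  if (length(height) != 1L || length(width) != 1L ||
      is.na(height) || is.na(width) || height < 1 || width < 1 ||
      height != as.integer(height) || width != as.integer(width)) {
    stop("height and width must be positive integers")
  }
  height <- as.integer(height)
  width <- as.integer(width)
  d <- height * width

  idx <- pixelIndex(height, width, indexOrder)
  # vertical edges: (r, c) -- (r+1, c); horizontal: (r, c) -- (r, c+1)
  from <- integer(0)
  to <- integer(0)
  if (height > 1L) {
    r <- rep(seq_len(height - 1L), times = width)
    cc <- rep(seq_len(width), each = height - 1L)
    from <- c(from, idx[cbind(r, cc)])
    to <- c(to, idx[cbind(r + 1L, cc)])
  }
  if (width > 1L) {
    r <- rep(seq_len(height), times = width - 1L)
    cc <- rep(seq_len(width - 1L), each = height)
    from <- c(from, idx[cbind(r, cc)])
    to <- c(to, idx[cbind(r, cc + 1L)])
  }

  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                            dims = c(d, d))
  deg <- Matrix::rowSums(A)
  D <- Matrix::Diagonal(d, deg)
  L <- D - A
  new("GridGraph", height = height, width = width, d = d,
      adjacency = A, degree = D, laplacian = L, indexOrder = indexOrder)
}

# (row, col) -> vector index lookup matrix for a given order.
pixelIndex <- function(height, width, indexOrder) {
  if (indexOrder == "column_major") {
    matrix(seq_len(height * width), nrow = height, ncol = width)
  } else {
    matrix(seq_len(height * width), nrow = height, ncol = width, byrow = TRUE)
  }
}

#' Laplacian smoothness quadratic form
#'
#' Evaluates \eqn{w^T L w}, which equals half the sum of squared differences
#' \eqn{(w_i - w_j)^2} over all adjacent pixel pairs, so it is zero exactly
#' for vectors constant over each connected region and grows as neighbouring
#' weights disagree.
#'
#' @param graph a [GridGraph-class].
#' @param w numeric vector of length \code{graph@d}.
#' @return A nonnegative scalar.
#'
#' @examples
#' g <- buildGridGraph(1, 3)
#' quadraticForm(g, c(1, 2, 4))  # (1-2)^2 + (2-4)^2 = 5
#' @export
quadraticForm <- function(graph, w) {
  stopifnot(is(graph, "GridGraph"))
  if (length(w) != graph@d) {
    stop(sprintf("w has length %d but the grid has %d pixels",
                 length(w), graph@d))
  }
  sum(w * as.numeric(graph@laplacian %*% w))
}

#' Flatten an image to a vector / restore a vector to an image
#'
#' \code{vectorizeImage} flattens an \code{height} by \code{width} matrix into
#' a length-\code{height*width} vector in the given index order;
#' \code{unvectorizeImage} is its exact inverse. Using the same
#' \code{indexOrder} as the [GridGraph-class] keeps pixel values aligned with
#' graph vertices.
#'
#' @param img numeric matrix (height by width).
#' @param v numeric vector of length \code{height*width}.
#' @param height,width the grid dimensions.
#' @param indexOrder \code{"column_major"} (default) or \code{"row_major"}.
#' @return A vector (\code{vectorizeImage}) or a matrix
#'   (\code{unvectorizeImage}).
#' @export
vectorizeImage <- function(img, indexOrder = c("column_major", "row_major")) {
  indexOrder <- match.arg(indexOrder)
  stopifnot(is.matrix(img))
  if (indexOrder == "column_major") as.vector(img) else as.vector(t(img))
}

#' @rdname vectorizeImage
#' @export
unvectorizeImage <- function(v, height, width,
                             indexOrder = c("column_major", "row_major")) {
  indexOrder <- match.arg(indexOrder)
  if (length(v) != height * width) {
    stop("length(v) must equal height * width")
  }
  if (indexOrder == "column_major") {
    matrix(v, nrow = height, ncol = width)
  } else {
    matrix(v, nrow = height, ncol = width, byrow = TRUE)
  }
}
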