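#' Write and read plain (ASCII) PGM images
#'
#' Minimal portable-graymap I/O used for component rendering and for loading
#' image stacks from a directory. \code{writePGM} writes the P2 (plain text)
#' format with maxval 255; \code{readPGM} reads P2 files.
#'
#' @param img numeric matrix with values in [0, 255].
#' @param path file path.
#' @return \code{readPGM} returns a numeric matrix; \code{writePGM} the path,
#'   invisibly.
#' @export
writePGM <- function(img, path) {
  stopifnot(is.matrix(img))
  vals <- round(pmin(pmax(img, 0), 255))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  write(t(vals), file = con, ncolumns = ncol(img))
  invisible(path)
}

#' @rdname writePGM
#' @export
readPGM <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only plain (P2) PGM files are supported")
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM: wrong pixel count")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Render components as eigenface-style images
#'
#' Reshapes each column of the basis back to the image grid (inverting the
#' vectorization order), affinely rescales it to [0, 255] per component
#' (min-max; a constant component renders as uniform mid-gray), and writes
#' one PGM file per component. The raw values are untouched; rescaling is for
#' display only.
#'
#' @param basis a [ProjectionBasis-class] or d-by-r matrix.
#' @param height,width image grid dimensions (d = height * width).
#' @param dir output directory (created if missing).
#' @param indexOrder vectorization order used when the images were flattened.
#' @param prefix filename prefix.
#' @return Character vector of written file paths, invisibly.
#' @export
renderComponents <- function(basis, height, width, dir,
                             indexOrder = c("column_major", "row_major"),
                             prefix = "component") {
  indexOrder <- match.arg(indexOrder)
  W <- if (is(basis, "ProjectionBasis")) basis@W else as.matrix(basis)
  if (nrow(W) != height * width) {
    stop("basis dimension does not match height * width")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ncol(W))
  for (j in seq_len(ncol(W))) {
    img <- unvectorizeImage(W[, j], height, width, indexOrder)
    rng <- range(img)
    disp <- if (diff(rng) == 0) {
      matrix(127.5, height, width)
    } else {
      (img - rng[1]) / diff(rng) * 255
    }
    paths[j] <- file.path(dir, sprintf("%s_%03d.pgm", prefix, j))
    writePGM(disp, paths[j])
  }
  invisible(paths)
}

#' Load an image stack from a directory or a delimited matrix file
#'
#' \code{readImageDirectory} reads every .pgm (plain P2) and, when the png
#' package is available, .png file in a directory (sorted by name), checks
#' that all images share one size, and vectorizes them into a d-by-n matrix.
#' Subdirectory-free class labels can be supplied separately.
#' \code{readMatrixFile} reads a whitespace- or comma-delimited numeric
#' matrix, one vectorized image per column.
#'
#' @param dir directory of image files.
#' @param path delimited text file.
#' @param indexOrder vectorization order.
#' @return \code{readImageDirectory}: list with \code{X}, \code{height},
#'   \code{width}, \code{files}; \code{readMatrixFile}: a numeric matrix.
#' @export
readImageDirectory <- function(dir,
                               indexOrder = c("column_major", "row_major")) {
  indexOrder <- match.arg(indexOrder)
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.(pgm|png)$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no .pgm or .png images found in ", dir)
  imgs <- lapply(files, function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      if (!requireNamespace("png", quietly = TRUE)) {
        stop("the png package is required to read PNG files")
      }
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m * 255
    } else {
      readPGM(f)
    }
  })
  dims <- vapply(imgs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all images must share one size")
  }
  X <- vapply(imgs, vectorizeImage, numeric(prod(dims[, 1])),
              indexOrder = indexOrder)
  list(X = X, height = dims[1, 1], width = dims[2, 1], files = files)
}

#' @rdname readImageDirectory
#' @export
readMatrixFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  as.matrix(utils::read.table(path, sep = sep, header = FALSE))
}
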