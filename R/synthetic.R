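#' Construct a synthetic image-stack specification
#'
#' Defaults describe the package's desk-scale study conditions: a 16 x 16
#' grid, 100 images, one planted component with 70 percent exact zeros built
#' from Gaussian blobs of radius 2, background noise of sd 0.1 against a unit
#' leading score variance, no occlusions and no class structure.
#'
#' @param height,width grid dimensions (at least 4).
#' @param n number of images.
#' @param nComponentsTrue number of planted components.
#' @param sparsity fraction of zero pixels per component.
#' @param smoothScale blob radius in pixels.
#' @param noiseSd additive Gaussian noise sd.
#' @param outlierFraction fraction of images occluded.
#' @param nClasses number of classes (0 for unlabelled).
#' @param seed master seed.
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(height = 16L, width = 16L, n = 100L,
                          nComponentsTrue = 1L, sparsity = 0.7,
                          smoothScale = 2, noiseSd = 0.1,
                          outlierFraction = 0, nClasses = 0L, seed = 1L) {
  new("SyntheticSpec", height = as.integer(height), width = as.integer(width),
      n = as.integer(n), nComponentsTrue = as.integer(nComponentsTrue),
      sparsity = as.numeric(sparsity), smoothScale = as.numeric(smoothScale),
      noiseSd = as.numeric(noiseSd),
      outlierFraction = as.numeric(outlierFraction),
      nClasses = as.integer(nClasses), seed = as.integer(seed))
}

# One sparse-smooth pattern on the grid: Gaussian-profile blobs inside a
# contiguous rectangular support, exact zeros elsewhere, unit L2 norm.
# `band` optionally restricts the support to a column range (used to keep
# multiple components on disjoint supports, hence exactly orthogonal).
sparseSmoothPattern <- function(height, width, sparsity, smoothScale,
                                band = NULL) {
  d <- height * width
  targetArea <- max(1, round((1 - sparsity) * d))
  if (is.null(band)) band <- c(1L, width)
  bandWidth <- band[2] - band[1] + 1L
  # pick a support rectangle of about targetArea pixels inside the band
  wSide <- min(bandWidth, max(1L, ceiling(sqrt(targetArea))))
  hSide <- min(height, max(1L, ceiling(targetArea / wSide)))
  wSide <- min(bandWidth, max(1L, ceiling(targetArea / hSide)))
  if (hSide * wSide < 1) stop("infeasible sparsity/support combination")
  r0 <- sample.int(height - hSide + 1L, 1L)
  c0 <- band[1] + sample.int(bandWidth - wSide + 1L, 1L) - 1L

  img <- matrix(0, height, width)
  rows <- r0:(r0 + hSide - 1L)
  cols <- c0:(c0 + wSide - 1L)
  nBlobs <- max(1L, round(hSide * wSide / max(1, (2 * smoothScale + 1)^2)))
  nBlobs <- min(nBlobs, 4L)
  for (b in seq_len(nBlobs)) {
    cy <- stats::runif(1, min(rows), max(rows))
    cx <- stats::runif(1, min(cols), max(cols))
    amp <- stats::runif(1, 0.5, 1)
    for (rr in rows) {
      img[rr, cols] <- img[rr, cols] +
        amp * exp(-((rr - cy)^2 + (cols - cx)^2) / (2 * smoothScale^2))
    }
  }
  out <- matrix(0, height, width)
  out[rows, cols] <- img[rows, cols]
  out
}

#' Planted sparse smooth components
#'
#' Builds \code{nComponentsTrue} unit-norm components on the image grid, each
#' a sum of Gaussian-profile blobs of radius \code{smoothScale} inside a
#' contiguous support covering about \code{1 - sparsity} of the pixels, with
#' exact zeros elsewhere. Supports are placed on disjoint column bands
#' whenever they fit, making the components exactly orthogonal; otherwise
#' they are Gram-Schmidt orthogonalized (which can erode the exact-zero
#' fraction, so high \code{nComponentsTrue} with low \code{sparsity} is
#' discouraged).
#'
#' @param spec a [SyntheticSpec-class].
#' @return A list with \code{W} (d by k, unit columns), \code{support}
#'   (d by k logical matrix of nonzero masks) and the [GridGraph-class] used.
#' @export
makeTrueComponents <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  h <- spec@height
  w <- spec@width
  k <- spec@nComponentsTrue
  d <- h * w
  if ((1 - spec@sparsity) * d < 1) {
    stop("sparsity too high: empty support")
  }
  graph <- buildGridGraph(h, w)
  withSeed(subSeed(spec@seed, 101L), {
    targetArea <- max(1, round((1 - spec@sparsity) * d))
    bandNeeded <- ceiling(targetArea / h)
    disjoint <- k * bandNeeded <= w
    W <- matrix(0, d, k)
    for (j in seq_len(k)) {
      band <- if (disjoint) {
        lo <- 1L + (j - 1L) * (w %/% k)
        c(lo, min(w, lo + max(bandNeeded, w %/% k) - 1L))
      } else NULL
      img <- sparseSmoothPattern(h, w, spec@sparsity, spec@smoothScale, band)
      W[, j] <- vectorizeImage(img)
    }
    if (!disjoint && k > 1) {
      for (j in 2:k) {
        for (i in 1:(j - 1)) {
          W[, j] <- W[, j] - sum(W[, j] * W[, i]) /
            sum(W[, i]^2) * W[, i]
        }
      }
    }
    W <- apply(W, 2, unitize)
    list(W = W, support = W != 0, graph = graph)
  })
}

#' Simulate an image stack with planted structure
#'
#' Generates \eqn{X = m_0 + W_{true} S + E}: a fixed smooth baseline image
#' \eqn{m_0} shared by every sample (the analogue of the mean image that puts
#' real stacks on a nonnegative intensity scale; it is removed exactly by
#' mean-centering), plus planted structure and noise. Scores \eqn{S} are
#' Gaussian with
#' per-component variances decaying geometrically (ratio 0.5, leading
#' variance 1) so component order is identifiable, and \eqn{E} is iid
#' Gaussian noise of sd \code{noiseSd}. A fraction \code{outlierFraction} of
#' images is then corrupted with rectangular salt-and-pepper occlusions
#' (sides about 0.3 to 0.6 of the shorter grid side, scaled-down analogues
#' of occlusions on full-size face images). When \code{nClasses > 0},
#' class-specific mean offsets — themselves sparse-smooth patterns, so the
#' discriminative signal matches the structure the solvers favour — are
#' added and labels returned.
#'
#' @param spec a [SyntheticSpec-class].
#' @return A list with \code{X} (d by n), \code{labels} (or NULL), and
#'   \code{truth}: a list holding \code{W} (planted components),
#'   \code{scores}, \code{occluded} (column indices), \code{classMeans}
#'   (d by nClasses or NULL) and the [GridGraph-class].
#' @export
makeDataset <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  truthW <- makeTrueComponents(spec)
  d <- spec@height * spec@width
  k <- spec@nComponentsTrue
  n <- spec@n

  sds <- sqrt(0.5)^(seq_len(k) - 1)
  S <- withSeed(subSeed(spec@seed, 202L), {
    matrix(stats::rnorm(k * n, sd = rep(sds, n)), nrow = k)
  })
  E <- withSeed(subSeed(spec@seed, 303L), {
    matrix(stats::rnorm(d * n, sd = spec@noiseSd), nrow = d)
  })
  # Fixed baseline image shared by all samples: real image stacks live on a
  # nonnegative intensity scale with a structured mean image, and it is this
  # baseline that makes salt-and-pepper extremes coherent outliers after
  # centering. It is identical across samples, so mean-centering removes it
  # exactly and clean-data analyses are unaffected.
  baseline <- withSeed(subSeed(spec@seed, 50L), {
    field <- sparseSmoothPattern(spec@height, spec@width, sparsity = 0,
                                 smoothScale = max(spec@height, spec@width) / 3)
    f <- vectorizeImage(field)
    3 * (f - min(f)) / max(f - min(f))
  })
  X <- baseline + truthW$W %*% S + E

  labels <- NULL
  classMeans <- NULL
  if (spec@nClasses > 0L) {
    C <- spec@nClasses
    labels <- rep(seq_len(C), length.out = n)
    classMeans <- withSeed(subSeed(spec@seed, 404L), {
      M <- vapply(seq_len(C), function(cl) {
        vectorizeImage(sparseSmoothPattern(spec@height, spec@width,
                                           spec@sparsity, spec@smoothScale))
      }, numeric(d))
      apply(M, 2, unitize) * 1.5  # effect size relative to unit score sd
    })
    X <- X + classMeans[, labels]
  }

  occluded <- integer(0)
  if (spec@outlierFraction > 0) {
    side <- min(spec@height, spec@width)
    occSpec <- occlusionSpec(fraction = spec@outlierFraction,
                             minSide = max(2L, floor(0.3 * side)),
                             maxSide = max(2L, floor(0.6 * side)),
                             seed = subSeed(spec@seed, 505L))
    occ <- occlude(X, spec@height, spec@width, occSpec)
    X <- occ$X
    occluded <- occ$occluded
  }

  list(X = X, labels = labels,
       truth = list(W = truthW$W, support = truthW$support, scores = S,
                    baseline = baseline, occluded = occluded,
                    classMeans = classMeans, graph = truthW$graph))
}
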