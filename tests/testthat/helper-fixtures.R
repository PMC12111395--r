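# Shared fixtures: everything generated in code, nothing stored on disk.

randomStack <- function(d, n, seed) {
  set.seed(seed)
  matrix(rnorm(d * n), d, n)
}

# Leading left singular vector, the shared initialization of every solver.
leadVector <- function(X) as.numeric(svd(X, nu = 1, nv = 0)$u[, 1])

# Independent oracle for the Laplacian quadratic form: half the sum of
# squared differences over all ordered adjacent pixel pairs, enumerated from
# pixel coordinates (never through the Laplacian matrix).
bruteSmoothness <- function(height, width, w, indexOrder = "column_major") {
  idx <- if (indexOrder == "column_major") {
    matrix(seq_len(height * width), height, width)
  } else {
    matrix(seq_len(height * width), height, width, byrow = TRUE)
  }
  coords <- expand.grid(r = seq_len(height), c = seq_len(width))
  tot <- 0
  for (a in seq_len(nrow(coords))) {
    for (b in seq_len(nrow(coords))) {
      dist <- sqrt((coords$r[a] - coords$r[b])^2 +
                   (coords$c[a] - coords$c[b])^2)
      if (isTRUE(all.equal(dist, 1))) {
        ia <- idx[coords$r[a], coords$c[a]]
        ib <- idx[coords$r[b], coords$c[b]]
        tot <- tot + (w[ia] - w[ib])^2
      }
    }
  }
  tot / 2
}

# Random orthonormal d x r basis via QR of a Gaussian matrix.
randomOrthonormal <- function(d, r, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * r), d, r)))[, seq_len(r), drop = FALSE]
}

relDiffs <- function(traj) diff(traj) / pmax(traj[-length(traj)], 1e-300)
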