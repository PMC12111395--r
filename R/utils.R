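# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. seed = NA means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.na(seed)) return(eval.parent(substitute(expr)))
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Derive a reproducible sub-seed from a master seed and a stream label,
# kept strictly below 2^31.
subSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483587) + 1L
}

l2norm <- function(x) sqrt(sum(x^2))

unitize <- function(x) {
  n <- l2norm(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

# Flip a vector (or each column of a matrix) so its largest-magnitude entry is
# positive. The L1 objective is sign-invariant, so this is pure convention;
# applied only after convergence so the MM ascent property is untouched.
signFix <- function(w) {
  if (is.matrix(w)) {
    for (j in seq_len(ncol(w))) w[, j] <- signFix(w[, j])
    return(w)
  }
  i <- which.max(abs(w))
  if (length(i) && w[i] < 0) -w else w
}

assertScalarCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1 || x != as.integer(x)) {
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  }
  as.integer(x)
}

asTrainingMatrix <- function(X, grid = NULL) {
  if (is(X, "TrainingMatrix")) return(X)
  if (!is.matrix(X)) X <- as.matrix(X)
  new("TrainingMatrix", X = X, center = numeric(nrow(X)), grid = grid)
}
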