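# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state so package functions do not
# disturb the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# round() uses round-half-to-even; the split/AD conventions here are
# round-half-up on non-negative quantities.
round_half_up <- function(x) floor(x + 0.5)

# Near-equal random fold labels 1..k for n samples.
make_folds <- function(n, k, seed) {
  if (k < 2L || k > n) stop("number of folds must be in [2, n]", call. = FALSE)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == as.integer(x)
}

# Squared Euclidean cross-distances between rows of A (queries) and B
# (references); clamped at zero against negative round-off.
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}
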