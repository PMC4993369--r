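#' @keywords internal
"_PACKAGE"

# Deterministic child-seed derivation: every stochastic operation draws its
# own seed from the master seed and a string key, so adding or reordering
# operations never perturbs the streams of the others.  The hash is a plain
# polynomial rolling hash over the key's UTF-8 bytes, folded into [0, 2^31).
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG stream seeded from (seed, key), restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(seed, key))
  expr
}

# log2 with the package's pseudocount convention: value + 0.01 x the
# genome-wide median of the nonzero values (keeps ranking, avoids -Inf).
log2_pseudo <- function(x, pseudocount = NULL) {
  if (is.null(pseudocount)) {
    nz <- x[is.finite(x) & x > 0]
    pseudocount <- if (length(nz)) 0.01 * stats::median(nz) else 1e-3
  }
  list(value = log2(x + pseudocount), pseudocount = pseudocount)
}

# Inverse of the trigamma function by Newton iteration; used by the
# empirical-Bayes variance moderation to turn a moment estimate into a
# prior degrees-of-freedom.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
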