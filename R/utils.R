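#' Tucker congruence coefficient
#'
#' Cosine similarity between two loading (or direction) vectors, the standard
#' measure of factor/component similarity. For matrices, computed column-pair
#' wise, returning a `ncol(x)` x `ncol(y)` matrix.
#'
#' @param x,y Numeric vectors of equal length, or matrices with equal row
#'   counts.
#' @return A scalar in [-1, 1], or a matrix of such values.
#' @export
tucker_congruence <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y))
  num <- crossprod(x, y)
  den <- sqrt(colSums(x^2)) %o% sqrt(colSums(y^2))
  out <- num / den
  if (length(out) == 1L) out[1L] else out
}

# Deterministic child seed from a master seed and a tag. Adding a new tagged
# block never perturbs draws made under other tags. Kept below 2^31.
child_seed <- function(master, tag) {
  h <- as.double(master %% 2147483647L)
  for (k in utf8ToInt(paste0(":", tag))) {
    h <- (h * 31 + k) %% 2147483629
  }
  as.integer(h)
}

# Run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
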