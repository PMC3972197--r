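# Small shared helpers.

#' Round half away from zero
#'
#' Nearest-integer rounding with halves rounded away from zero, as used by the
#' validity-index decision fusion (base `round()` rounds half to even, which
#' would turn a fused mean of 2.5 into 2).
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @keywords internal
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Adjusted Rand Index between two partitions
#'
#' Label-permutation-invariant agreement between two clusterings of the same
#' items. 1 means identical partitions, 0 the expected value under random
#' labelings.
#'
#' @param a,b Integer (or factor) label vectors of equal length.
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Squared Euclidean distances between rows of x and rows of centers.
# Returns an nrow(x) x nrow(centers) matrix.
rowdist2 <- function(x, centers) {
  x2 <- rowSums(x^2)
  c2 <- rowSums(centers^2)
  d2 <- outer(x2, c2, "+") - 2 * tcrossprod(x, centers)
  d2[d2 < 0] <- 0
  d2
}

# Derive a reproducible sub-seed from a base seed and a stream index, kept
# well below .Machine$integer.max.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103 + as.double(stream) * 7919) %% 2147483629)
}

# md5 of an arbitrary R object (via a temporary serialized file); used to
# stamp output bundles with a config hash.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}
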