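# Cluster-separation statistic and its significance under two null models.
#
# The statistic averages, over cluster pairs, the distance between the two
# centroids normalized by the between-clusters variation of the pooled pair
# (standard deviation of the pooled members' distances to the pooled
# centroid). Significance is assessed by rank against label draws that
# either ignore the observed cluster sizes (randomization test) or preserve
# the label multiset (permutation test).

#' Cluster separation statistic
#'
#' `S = (2 / (K (K - 1))) * sum_{a<b} d(c_a, c_b) / sigma_ab` with `d` the
#' Euclidean centroid distance and `sigma_ab` the (sample) standard
#' deviation of the distances of the pooled members of clusters a and b to
#' their pooled centroid. `S` is translation and rotation invariant; if some
#' pooled pair is a single repeated point (`sigma_ab = 0`) the statistic is
#' `Inf`.
#'
#' @param X Numeric matrix or `feature_matrix`.
#' @param labels Integer cluster labels, K >= 2 non-empty clusters.
#' @return Numeric scalar >= 0 (possibly `Inf`).
#' @export
cluster_separation <- function(X, labels) {
  X <- as_feature_X(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  if (K < 2L) stop("cluster separation is undefined for K = 1")
  idx <- lapply(ks, function(k) which(labels == k))
  cents <- lapply(idx, function(ii) colMeans(X[ii, , drop = FALSE]))
  tot <- 0
  for (a in 1:(K - 1L)) for (b in (a + 1L):K) {
    dab <- sqrt(sum((cents[[a]] - cents[[b]])^2))
    ii <- c(idx[[a]], idx[[b]])
    pooled <- X[ii, , drop = FALSE]
    pc <- colMeans(pooled)
    dd <- sqrt(rowSums(sweep(pooled, 2L, pc, "-")^2))
    sab <- stats::sd(dd)
    tot <- tot + (if (sab == 0) {
      if (dab == 0) 0 else Inf
    } else dab / sab)
  }
  2 * tot / (K * (K - 1))
}

#' Significance of the cluster separation
#'
#' Recomputes the separation statistic under `n_perm` null label
#' assignments and reports the rank p-value
#' `p = (1 + #\{S_null >= S_obs\}) / (1 + n_perm)`. In `"randomization"`
#' mode every sample is assigned to one of the K clusters uniformly at
#' random (draws leaving a cluster empty are rejected and redrawn); in
#' `"permutation"` mode the observed label multiset is shuffled, preserving
#' the cluster sizes.
#'
#' @inheritParams cluster_separation
#' @param n_perm Number of null draws (>= 100; the study-scale setting of
#'   1e6 is reachable, the default is desk-scale).
#' @param mode `"permutation"`, `"randomization"`, or `"both"`.
#' @param seed Integer RNG seed.
#' @return A `separation_test_result`: list with `S_observed`, `n_perm`,
#'   `p_randomization`, `p_permutation` (NA for modes not run), `seed`.
#' @export
separation_test <- function(X, labels, n_perm = 10000L,
                            mode = c("both", "randomization", "permutation"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 100L)
  X <- as_feature_X(X)
  n <- nrow(X)
  K <- length(unique(labels))
  S_obs <- cluster_separation(X, labels)
  run_null <- function(draw) {
    count <- 0L
    for (i in seq_len(n_perm)) {
      s <- cluster_separation(X, draw())
      if (s >= S_obs) count <- count + 1L
    }
    (1 + count) / (1 + n_perm)
  }
  p_rand <- NA_real_
  p_perm <- NA_real_
  set.seed(seed)
  if (mode %in% c("both", "randomization")) {
    draw_rand <- function() {
      repeat {
        l <- sample.int(K, n, replace = TRUE)
        if (length(unique(l)) == K) return(l)
      }
    }
    p_rand <- run_null(draw_rand)
  }
  if (mode %in% c("both", "permutation")) {
    draw_perm <- function() sample(labels)
    p_perm <- run_null(draw_perm)
  }
  structure(list(S_observed = S_obs, n_perm = as.integer(n_perm),
                 p_randomization = p_rand, p_permutation = p_perm,
                 seed = seed),
            class = "separation_test_result")
}

#' @export
print.separation_test_result <- function(x, ...) {
  cat(sprintf(
    "separation_test: S = %.4f, n_perm = %d, p_rand = %s, p_perm = %s\n",
    x$S_observed, x$n_perm, format(x$p_randomization),
    format(x$p_permutation)))
  invisible(x)
}
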