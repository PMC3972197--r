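# Cluster-number estimation by decision fusion of four validity indices:
# Dunn, Calinski-Harabasz, the gap statistic and the Laplacian eigengap of
# the self-tuning affinity. The indices need not agree; their votes are
# averaged and rounded to the nearest integer (half up), so e.g. votes
# {3, 2, 3, 3} fuse to 3 and {2, 2, 1, 3} fuse to 2.

#' Dunn index
#'
#' Minimum between-cluster single-linkage distance over the maximum
#' within-cluster diameter (Euclidean). Larger is better. If every cluster
#' has zero diameter (singletons or duplicated points) the index is `Inf`.
#'
#' @param X Numeric matrix or `feature_matrix`.
#' @param labels Integer cluster labels (>= 2 non-empty clusters).
#' @return Numeric scalar (possibly `Inf`).
#' @export
dunn_index <- function(X, labels) {
  X <- as_feature_X(X)
  ks <- sort(unique(labels))
  stopifnot(length(ks) >= 2L)
  d <- as.matrix(stats::dist(X))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  max_diam <- max(d[same & !is.na(same)], 0)
  min_inter <- min(d[!same & !is.na(same)])
  if (max_diam == 0) return(Inf)
  min_inter / max_diam
}

#' Calinski-Harabasz index
#'
#' `[tr(B)/(K-1)] / [tr(W)/(n-K)]` with B and W the between- and
#' within-cluster scatter about the centroids. Larger is better; `Inf` when
#' all clusters are exact points (W = 0).
#'
#' @inheritParams dunn_index
#' @return Numeric scalar (possibly `Inf`).
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as_feature_X(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  n <- nrow(X)
  if (K < 2L || K >= n) stop("requires 2 <= K < n")
  grand <- colMeans(X)
  trW <- 0; trB <- 0
  for (k in ks) {
    xk <- X[labels == k, , drop = FALSE]
    ck <- colMeans(xk)
    trW <- trW + sum(sweep(xk, 2L, ck, "-")^2)
    trB <- trB + nrow(xk) * sum((ck - grand)^2)
  }
  if (trW == 0) return(Inf)
  (trB / (K - 1)) / (trW / (n - K))
}

# total within-cluster sum of squares of a partition (k = 1 allowed)
within_ss <- function(X, labels) {
  tot <- 0
  for (k in unique(labels)) {
    xk <- X[labels == k, , drop = FALSE]
    tot <- tot + sum(sweep(xk, 2L, colMeans(xk), "-")^2)
  }
  tot
}

#' Gap statistic estimate of the cluster number
#'
#' Compares `log W_k` of the clustered data with its expectation under `B`
#' reference data sets drawn uniformly over the feature bounding box
#' (Tibshirani et al.'s simpler reference). The chosen k is the smallest k
#' with `Gap(k) >= Gap(k+1) - s_{k+1}` (1-SE rule); unlike the other
#' indices, k = 1 is admissible.
#'
#' @param X Numeric matrix or `feature_matrix`.
#' @param k_range Integer vector of candidate k (from 1).
#' @param B Number of reference draws (>= 10).
#' @param seed Integer RNG seed (required).
#' @param restarts K-means restarts per fit (references use cheap fits).
#' @return List with `k` (the estimate), `gap`, `se`, `log_w`.
#' @export
gap_statistic <- function(X, k_range = 1:6, B = 100L, seed, restarts = 5L) {
  X <- as_feature_X(X)
  stopifnot(B >= 10L)
  k_range <- sort(unique(as.integer(k_range)))
  n <- nrow(X)
  k_range <- k_range[k_range <= n]
  if (all(apply(X, 2L, function(c) stats::var(c) == 0)))
    return(list(k = 1L, gap = NULL, se = NULL, log_w = NULL))
  set.seed(seed)
  fit_w <- function(Y, k) {
    if (k == 1L) within_ss(Y, rep(1L, nrow(Y)))
    else kmeans_restarts(Y, k, restarts)$inertia
  }
  log_w <- log(pmax(vapply(k_range, function(k) fit_w(X, k), 0), 1e-300))
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  log_w_ref <- matrix(0, B, length(k_range))
  for (b in seq_len(B)) {
    ref <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
    log_w_ref[b, ] <- log(pmax(vapply(k_range, function(k) fit_w(ref, k), 0),
                               1e-300))
  }
  gap <- colMeans(log_w_ref) - log_w
  sdk <- apply(log_w_ref, 2L, function(col) sqrt(mean((col - mean(col))^2)))
  se <- sdk * sqrt(1 + 1 / B)
  k_hat <- k_range[length(k_range)]
  for (i in seq_len(length(k_range) - 1L)) {
    if (gap[i] >= gap[i + 1L] - se[i + 1L]) { k_hat <- k_range[i]; break }
  }
  list(k = as.integer(k_hat),
       gap = stats::setNames(gap, k_range),
       se = stats::setNames(se, k_range),
       log_w = stats::setNames(log_w, k_range))
}

#' Cluster number from the Laplacian eigengap
#'
#' Builds the self-tuning affinity, forms the symmetric normalized Laplacian
#' `L = I - D^{-1/2} A D^{-1/2}` and returns the position of the largest gap
#' in its ascending eigenvalue sequence within `1..k_max` (for k
#' well-separated components, L has k near-zero eigenvalues followed by a
#' jump).
#'
#' @param X Numeric matrix or `feature_matrix` (n >= 3).
#' @param k_max Largest admissible k.
#' @param n_neighbor Local-scale neighbor index.
#' @return Integer k estimate.
#' @export
affinity_eigen_estimate <- function(X, k_max = 6L, n_neighbor = 7L) {
  X <- as_feature_X(X)
  n <- nrow(X)
  stopifnot(n >= 3L)
  A <- self_tuning_affinity(X, n_neighbor)
  lam <- sort(1 - eigen(normalized_affinity(A), symmetric = TRUE,
                        only.values = TRUE)$values)
  k_max <- min(k_max, n - 1L)
  gaps <- lam[2:(k_max + 1L)] - lam[1:k_max]
  as.integer(which.max(gaps))
}

#' Fuse validity-index votes into one cluster number
#'
#' Nearest integer of the arithmetic mean of the votes; halves round away
#' from zero (the only worked value in the source material, mean 2.75, does
#' not disambiguate the half case).
#'
#' @param votes Integer vector of k votes (length >= 1).
#' @return Integer fused k.
#' @export
decision_fusion <- function(votes) {
  votes <- as.integer(votes)
  if (length(votes) < 1L) stop("decision_fusion requires at least one vote")
  round_half_up(mean(votes))
}

#' Estimate the cluster number by decision fusion
#'
#' Computes the four votes — Dunn and Calinski-Harabasz maximized over
#' partitions at each k >= 2 (these indices cannot vote 1), the gap
#' statistic (k = 1 admissible) and the Laplacian eigengap — and fuses them
#' by rounded mean.
#'
#' @param X Numeric matrix or `feature_matrix`.
#' @param k_range Candidate k values (default 1..6; the cohort scale makes
#'   larger k meaningless).
#' @param seed Integer RNG seed.
#' @param B Gap-statistic reference draws.
#' @param partition_fn Function `(X, K, seed)` producing partitions scored
#'   by Dunn/CH; defaults to [kmeans_cluster()].
#' @param restarts Restarts for the internal partitions.
#' @param n_neighbor Local-scale neighbor index for the eigengap vote.
#' @return A `validity_report`: list with `votes` (named integer vector),
#'   `k_range`, `fused_k`, `seed`.
#' @export
estimate_cluster_number <- function(X, k_range = 1:6, seed, B = 100L,
                                    partition_fn = NULL, restarts = 20L,
                                    n_neighbor = 7L) {
  Xm <- as_feature_X(X)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 1L & k_range < nrow(Xm)]
  if (is.null(partition_fn))
    partition_fn <- function(X, K, seed)
      kmeans_cluster(X, K, seed, restarts = restarts)
  ks2 <- k_range[k_range >= 2L]
  dunn_v <- ch_v <- rep(NA_real_, length(ks2))
  for (i in seq_along(ks2)) {
    part <- partition_fn(Xm, ks2[i], derive_seed(seed, ks2[i]))
    dunn_v[i] <- dunn_index(Xm, part$labels)
    ch_v[i] <- calinski_harabasz(Xm, part$labels)
  }
  votes <- c(
    dunn = ks2[which.max(dunn_v)],
    calinski_harabasz = ks2[which.max(ch_v)],
    gap = gap_statistic(Xm, k_range, B, derive_seed(seed, 101L))$k,
    affinity_eigen = affinity_eigen_estimate(Xm, max(k_range), n_neighbor)
  )
  structure(list(votes = votes, k_range = k_range,
                 fused_k = decision_fusion(votes), seed = seed),
            class = "validity_report")
}

#' @export
print.validity_report <- function(x, ...) {
  cat("validity_report: votes",
      paste(sprintf("%s=%d", names(x$votes), x$votes), collapse = ", "),
      "-> fused k =", x$fused_k, "\n")
  invisible(x)
}
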