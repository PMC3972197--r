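# Lesion-trajectory clustering: self-tuning spectral clustering (NJW
# procedure with locally scaled affinities) and a plain K-means baseline.
# K-means is implemented in-package (k-means++ seeding, Lloyd iterations,
# empty-cluster repair by re-seeding at the farthest point) so that restarts,
# determinism and repair behave exactly as specified.

as_feature_X <- function(X) {
  if (inherits(X, "feature_matrix")) X$X else as.matrix(X)
}

#' Self-tuning (locally scaled) affinity matrix
#'
#' `A_ij = exp(-d^2(x_i, x_j) / (sigma_i sigma_j))` where `sigma_i` is the
#' Euclidean distance from point i to its `n_neighbor`-th nearest neighbor
#' (Zelnik-Manor & Perona's local scaling; their published default is the
#' 7th neighbor). With fewer points than neighbors, or for duplicated points
#' (zero scale), `sigma_i` is clamped to the smallest positive distance in
#' the data (1 if all points coincide). The diagonal is 0.
#'
#' @param X Numeric matrix or `feature_matrix` (rows = points).
#' @param n_neighbor Neighbor index for the local scale (default 7).
#' @return n x n symmetric affinity matrix with zero diagonal.
#' @export
self_tuning_affinity <- function(X, n_neighbor = 7L) {
  X <- as_feature_X(X)
  n <- nrow(X)
  stopifnot(n >= 2L)
  d <- as.matrix(stats::dist(X))
  pos <- d[d > 0]
  clamp <- if (length(pos) > 0L) min(pos) else 1
  k <- min(n_neighbor, n - 1L)
  sigma <- apply(d, 1L, function(row) sort(row[-which.min(row)])[k])
  # row[-which.min(row)] drops one zero (self); sort ascending, take k-th
  sigma[!is.finite(sigma) | sigma <= 0] <- clamp
  A <- exp(-d^2 / tcrossprod(sigma))
  diag(A) <- 0
  dimnames(A) <- NULL
  A
}

# Symmetric normalized affinity D^{-1/2} A D^{-1/2}; isolated points (zero
# degree) get degree 1 so the matrix stays finite.
normalized_affinity <- function(A) {
  deg <- rowSums(A)
  deg[deg <= 0] <- 1
  dinv <- 1 / sqrt(deg)
  A * tcrossprod(dinv)
}

# Deterministic eigen-decomposition: fix each eigenvector's sign so its
# first nonzero coordinate is positive (degenerate eigenvalues are returned
# in eigen()'s stable LAPACK order).
eigen_deterministic <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-12)
    if (length(nz) > 0L && V[nz[1], j] < 0) V[, j] <- -V[, j]
  }
  list(values = e$values, vectors = V)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, later
# centers with probability proportional to squared distance to the nearest
# chosen center.
kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  if (K > 1L) for (k in 2:K) {
    d2 <- apply(rowdist2(X, centers[1:(k - 1L), , drop = FALSE]), 1L, min)
    if (sum(d2) <= 0) i <- sample.int(n, 1L)
    else i <- sample.int(n, 1L, prob = d2)
    centers[k, ] <- X[i, ]
  }
  centers
}

# One Lloyd run from given centers; empty clusters are re-seeded at the
# point farthest from its assigned center.
lloyd <- function(X, centers, iter_max = 100L) {
  K <- nrow(centers)
  labels <- integer(nrow(X))
  for (it in seq_len(iter_max)) {
    d2 <- rowdist2(X, centers)
    new_labels <- max.col(-d2, ties.method = "first")
    for (k in seq_len(K)) {
      if (!any(new_labels == k)) {
        far <- which.max(d2[cbind(seq_len(nrow(X)), new_labels)])
        centers[k, ] <- X[far, ]
        new_labels[far] <- k
        d2 <- rowdist2(X, centers)
      }
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    centers <- t(vapply(seq_len(K),
                        function(k) colMeans(X[labels == k, , drop = FALSE]),
                        numeric(ncol(X))))
  }
  inertia <- sum(rowdist2(X, centers)[cbind(seq_len(nrow(X)), labels)])
  list(labels = labels, centers = centers, inertia = inertia)
}

# Best of `restarts` k-means++ / Lloyd runs. Caller handles the RNG seed.
kmeans_restarts <- function(X, K, restarts = 50L, iter_max = 100L) {
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- lloyd(X, kmeanspp_init(X, K), iter_max)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

# Relabel clusters 1..K by descending size (ties by first occurrence) and
# reorder centroids accordingly.
relabel_by_size <- function(fit) {
  sizes <- tabulate(fit$labels, nbins = nrow(fit$centers))
  first <- vapply(seq_along(sizes),
                  function(k) min(c(which(fit$labels == k), Inf)), numeric(1))
  ord <- order(-sizes, first)
  remap <- integer(length(ord))
  remap[ord] <- seq_along(ord)
  fit$labels <- remap[fit$labels]
  fit$centers <- fit$centers[ord, , drop = FALSE]
  fit
}

new_cluster_model <- function(labels, K, centroids, algorithm, seed, inertia,
                              row_ids = NULL) {
  structure(list(labels = as.integer(labels), K = as.integer(K),
                 centroids = centroids, algorithm = algorithm,
                 seed = seed, inertia = inertia, row_ids = row_ids),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("cluster_model (%s): K = %d, n = %d, sizes = %s\n",
              x$algorithm, x$K, length(x$labels),
              paste(tabulate(x$labels, x$K), collapse = "/")))
  invisible(x)
}

# number of connected components of an affinity matrix, counting edges
# with weight above `eps`
n_components <- function(A, eps = 1e-8) {
  n <- nrow(A)
  seen <- logical(n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(A[v, ] > eps & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

# NJW embedding for a given affinity: row-normalized top-K eigenvectors of
# the symmetric normalized affinity.
njw_embedding <- function(A, K) {
  e <- eigen_deterministic(normalized_affinity(A))
  V <- e$vectors[, seq_len(K), drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  nrm[nrm == 0] <- 1
  V / nrm
}

#' Spectral clustering (NJW procedure)
#'
#' Forms an affinity matrix, takes the top-K eigenvectors of the symmetric
#' normalized affinity `D^{-1/2} A D^{-1/2}`, normalizes the rows to unit
#' length and runs K-means (k-means++, 50 restarts) in that eigenspace.
#' Cluster labels are renumbered by descending cluster size, so cluster 1
#' is always the largest pattern group.
#'
#' Three affinity scalings are available. `"ng_auto"` (default) uses a
#' global kernel width `A_ij = exp(-d^2 / (2 sigma^2))` with `sigma`
#' selected automatically over distance quantiles by minimizing the
#' K-means distortion of the resulting embedding (the selection rule of
#' the original NJW algorithm), skipping widths under which the affinity
#' graph falls apart into more than K components. `"local"` is
#' Zelnik-Manor/Perona self-tuning via [self_tuning_affinity()] (per-point
#' 7th-neighbor scales); it excels when clusters have similar sizes but
#' different densities, but on data dominated by one dense class it can
#' rank that class's internal diffusion modes above the small-cluster
#' splits (see the methods vignette). `"global"` uses a fixed supplied
#' `sigma`.
#'
#' @param X Numeric matrix or `feature_matrix`.
#' @param K Number of clusters, `2 <= K <= n` (K = n returns singletons).
#' @param seed Integer RNG seed (required for reproducibility).
#' @param scaling `"ng_auto"`, `"local"` or `"global"`.
#' @param n_neighbor Local-scale neighbor index for `scaling = "local"`.
#' @param sigma Kernel width for `scaling = "global"`.
#' @param restarts K-means restarts in the eigenspace.
#' @return A `cluster_model`: `labels` (1..K), `K`, `centroids` (in the
#'   original feature space), `algorithm`, `seed`, `inertia`, and the
#'   selected `sigma` when applicable.
#' @export
spectral_cluster <- function(X, K, seed,
                             scaling = c("ng_auto", "local", "global"),
                             n_neighbor = 7L, sigma = NULL,
                             restarts = 50L) {
  scaling <- match.arg(scaling)
  Xm <- as_feature_X(X)
  n <- nrow(Xm)
  if (K > n) stop("K > number of points")
  sigma_used <- NA_real_
  if (K == n) {
    fit <- list(labels = seq_len(n), centers = Xm, inertia = 0)
  } else {
    if (scaling == "local") {
      A <- self_tuning_affinity(Xm, n_neighbor)
    } else {
      d <- as.matrix(stats::dist(Xm))
      pos <- d[upper.tri(d)]
      pos <- pos[pos > 0]
      if (length(pos) == 0L) pos <- 1
      if (scaling == "global") {
        sigma_used <- if (is.null(sigma)) stats::median(pos) / 2 else sigma
      } else {
        # Ng's automatic kernel width: scan distance quantiles, keep
        # widths under which the graph has at most K components, pick the
        # one whose embedding clusters with least distortion
        cands <- unique(stats::quantile(pos, probs = seq(0.05, 0.95,
                                                         by = 0.05)))
        cands <- cands[cands > 0]
        best <- NULL
        set.seed(derive_seed(seed, 17L))
        for (s2 in cands) {
          A_c <- exp(-d^2 / (2 * s2^2))
          diag(A_c) <- 0
          if (n_components(A_c) > K) next
          U_c <- njw_embedding(A_c, K)
          fit_c <- kmeans_restarts(U_c, K, 5L)
          if (is.null(best) || fit_c$inertia < best$inertia)
            best <- list(sigma = s2, inertia = fit_c$inertia)
        }
        sigma_used <- if (is.null(best)) stats::median(pos) / 2
                      else best$sigma
      }
      A <- exp(-d^2 / (2 * sigma_used^2))
      diag(A) <- 0
    }
    U <- njw_embedding(A, K)
    set.seed(seed)
    fit <- kmeans_restarts(U, K, restarts)
  }
  fit <- relabel_by_size(fit)
  centroids <- t(vapply(seq_len(K), function(k)
    colMeans(Xm[fit$labels == k, , drop = FALSE]), numeric(ncol(Xm))))
  model <- new_cluster_model(fit$labels, K, centroids, "spectral", seed,
                             fit$inertia, rownames(Xm))
  model$scaling <- scaling
  model$sigma <- sigma_used
  model
}

#' K-means clustering baseline
#'
#' Lloyd's algorithm with k-means++ seeding and 50 restarts on the feature
#' matrix itself; labels renumbered by descending cluster size.
#'
#' @inheritParams spectral_cluster
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return A `cluster_model` (algorithm `"kmeans"`).
#' @export
kmeans_cluster <- function(X, K, seed, restarts = 50L, iter_max = 100L) {
  Xm <- as_feature_X(X)
  if (K > nrow(Xm)) stop("K > number of points")
  set.seed(seed)
  fit <- relabel_by_size(kmeans_restarts(Xm, K, restarts, iter_max))
  new_cluster_model(fit$labels, K, fit$centers, "kmeans", seed, fit$inertia,
                    rownames(Xm))
}
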