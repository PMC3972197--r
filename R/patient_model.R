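# Tier 2: patient profiles and outcome regression.
#
# Each patient is summarized by the cardinalities of the lesion-pattern
# clusters among their trajectories (n_i per cluster). Future chronic
# hypointense lesion load is regressed on these counts with a no-intercept
# least-squares model y = N beta (the intercept is neglected: every active
# patient has at least one nonzero count). Goodness of fit is reported as
# R^2, in-sample and under leave-one-patient-out / leave-one-lesion-out
# protocols.

#' Per-patient cluster cardinalities
#'
#' Counts, for every patient, how many of their lesion trajectories fall in
#' each cluster. Patients present only in the outcome table (no active
#' lesions) are carried through with all-zero counts and flagged group "C";
#' they are excluded from model fitting.
#'
#' @param labels Integer cluster labels, one per trajectory.
#' @param patient_ids Character vector, the patient of each trajectory.
#' @param K Number of clusters.
#' @param outcomes Optional data.frame with columns `patient_id`,
#'   `hypointense_m24_ml` and optionally `tll_m24_ml`; patients listed here
#'   but absent from `patient_ids` become zero-count (group C) rows.
#' @param severe_clusters Clusters whose presence marks group "A" (default
#'   all clusters but the first, i.e. the non-dominant patterns; cluster 1
#'   is the largest by construction).
#' @return A `patient_profiles` data.frame: `patient_id`, count columns
#'   `n1..nK`, `n_total`, outcome columns when supplied, and `group`
#'   ("A"/"B"/"C").
#' @export
patient_cardinalities <- function(labels, patient_ids, K, outcomes = NULL,
                                  severe_clusters = NULL) {
  stopifnot(length(labels) == length(patient_ids))
  if (any(labels < 1L | labels > K)) stop("labels must lie in 1..K")
  if (is.null(severe_clusters)) severe_clusters <- setdiff(seq_len(K), 1L)
  active <- sort(unique(patient_ids))
  extra <- character()
  if (!is.null(outcomes)) {
    if (!all(c("patient_id", "hypointense_m24_ml") %in% names(outcomes)))
      stop("outcomes needs patient_id and hypointense_m24_ml columns")
    outcomes$patient_id <- as.character(outcomes$patient_id)
    unknown <- setdiff(active, outcomes$patient_id)
    if (length(unknown) > 0L)
      stop("trajectories for patients missing from outcomes: ",
           paste(unknown, collapse = ", "))
    extra <- setdiff(outcomes$patient_id, active)
  }
  pats <- c(active, sort(extra))
  counts <- matrix(0L, length(pats), K,
                   dimnames = list(pats, paste0("n", seq_len(K))))
  tab <- table(factor(patient_ids, levels = active),
               factor(labels, levels = seq_len(K)))
  counts[active, ] <- as.integer(tab)
  df <- data.frame(patient_id = pats, counts, row.names = NULL,
                   stringsAsFactors = FALSE)
  df$n_total <- rowSums(counts)
  if (!is.null(outcomes)) {
    m <- match(df$patient_id, outcomes$patient_id)
    df$hypointense_m24_ml <- outcomes$hypointense_m24_ml[m]
    if ("tll_m24_ml" %in% names(outcomes))
      df$tll_m24_ml <- outcomes$tll_m24_ml[m]
  }
  severe <- rowSums(counts[, intersect(severe_clusters, seq_len(K)),
                           drop = FALSE])
  df$group <- ifelse(df$n_total == 0L, "C", ifelse(severe > 0L, "A", "B"))
  class(df) <- c("patient_profiles", "data.frame")
  df
}

#' Read the patient outcome table
#'
#' CSV with columns `patient_id`, `hypointense_m24_ml`, `tll_m24_ml` and
#' optionally `group` and `active` (0/1 flag for patients with active
#' lesions at the baseline time points).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("patient_id", "hypointense_m24_ml") %in% names(df)))
    stop("outcome table needs patient_id and hypointense_m24_ml columns")
  df$patient_id <- as.character(df$patient_id)
  df
}

#' No-intercept least-squares fit
#'
#' `beta = argmin ||N beta - y||^2` via the SVD pseudo-inverse, i.e. the
#' minimum-norm solution under rank deficiency (duplicated pattern columns
#' split their weight without changing predictions).
#'
#' @param N Numeric matrix (patients x K cardinalities).
#' @param y Outcome vector (chronic hypointense volume, ml).
#' @return Numeric coefficient vector, length `ncol(N)`.
#' @export
fit_linear_no_intercept <- function(N, y) {
  N <- as.matrix(N)
  if (nrow(N) != length(y)) stop("dimension mismatch")
  if (all(N == 0)) stop("design matrix is all zero")
  sv <- svd(N)
  tol <- max(dim(N)) * .Machine$double.eps * max(sv$d)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  drop(sv$v %*% (dinv * crossprod(sv$u, y)))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_res = sum (y_obs - y_pred)^2` and
#' `SS_tot = sum (y_obs - mean(y_obs))^2`. Equals 1 for a perfect fit, 0
#' for predicting the mean, and may be negative out of sample.
#'
#' @param y_pred,y_obs Numeric vectors of equal length >= 2.
#' @return Numeric scalar.
#' @export
r_squared <- function(y_pred, y_obs) {
  stopifnot(length(y_pred) == length(y_obs), length(y_obs) >= 2L)
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  if (ss_tot == 0) stop("R^2 undefined for constant observations")
  1 - sum((y_obs - y_pred)^2) / ss_tot
}

#' Leave-one-patient-out cross-validation
#'
#' For each fold one patient is held out, the model is refit on the rest
#' and the held-out outcome predicted. Reported are (a) the pooled
#' out-of-sample R^2 over all held-out predictions and (b) the mean and
#' variance across folds of the per-fold (training) R^2, since R^2 is not
#' defined for a single held-out point.
#'
#' @param N Patients x K cardinality matrix (active patients only).
#' @param y Outcome vector.
#' @return List with `pooled_r2`, `fold_r2_mean`, `fold_r2_var`, `fold_r2`,
#'   `predictions`.
#' @export
loo_patient_cv <- function(N, y) {
  N <- as.matrix(N)
  n <- nrow(N)
  if (n < 3L) stop("need at least 3 patients for leave-one-out")
  preds <- numeric(n)
  fold_r2 <- numeric(n)
  for (i in seq_len(n)) {
    beta <- fit_linear_no_intercept(N[-i, , drop = FALSE], y[-i])
    preds[i] <- sum(N[i, ] * beta)
    fold_r2[i] <- r_squared(drop(N[-i, , drop = FALSE] %*% beta), y[-i])
  }
  list(pooled_r2 = r_squared(preds, y),
       fold_r2_mean = mean(fold_r2),
       fold_r2_var = stats::var(fold_r2),
       fold_r2 = fold_r2,
       predictions = preds)
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

# Match clusters of a refit model to a reference by the label permutation
# minimizing total centroid distance (K is small, so enumeration is exact).
match_clusters_to_reference <- function(centroids, ref_centroids) {
  K <- nrow(ref_centroids)
  dmat <- sqrt(rowdist2(centroids, ref_centroids))
  best <- NULL; best_cost <- Inf
  for (p in all_permutations(K)) {
    cost <- sum(dmat[cbind(seq_len(K), p)])
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  best  # best[k] = reference label for refit cluster k
}

#' Leave-one-lesion-out cross-validation
#'
#' Each fold removes one trajectory, re-runs tier-1 clustering at fixed K,
#' re-derives the patient cardinalities (clusters matched back to the
#' full-data clustering by minimum total centroid distance), refits the
#' regression on the active patients and records the fit R^2. Folds whose
#' re-clustering produces an empty cluster are skipped and counted.
#'
#' @param fm `feature_matrix` over all trajectories.
#' @param outcomes Outcome data.frame (see [patient_cardinalities()]).
#' @param K Fixed number of clusters.
#' @param algorithm `"spectral"` or `"kmeans"`.
#' @param seed Integer RNG seed.
#' @param restarts K-means restarts per fold (folds are numerous; the
#'   default trades restarts for runtime).
#' @return List with `fold_r2_mean`, `fold_r2_var`, `fold_r2`, `skipped`.
#' @export
loo_lesion_cv <- function(fm, outcomes, K, algorithm = c("spectral", "kmeans"),
                          seed = 1L, restarts = 10L) {
  algorithm <- match.arg(algorithm)
  X <- fm$X
  n <- nrow(X)
  if (n < K + 1L) stop("need more trajectories than clusters")
  cluster_fn <- function(Xs, sd)
    if (algorithm == "spectral") spectral_cluster(Xs, K, sd, restarts = restarts)
    else kmeans_cluster(Xs, K, sd, restarts = restarts)
  full <- cluster_fn(X, seed)
  fold_r2 <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    fit <- cluster_fn(X[-i, , drop = FALSE], derive_seed(seed, i))
    if (length(unique(fit$labels)) < K) { skipped <- skipped + 1L; next }
    remap <- match_clusters_to_reference(fit$centroids, full$centroids)
    labels <- remap[fit$labels]
    prof <- patient_cardinalities(labels, fm$patient_ids[-i], K, outcomes)
    act <- prof[prof$n_total > 0L, , drop = FALSE]
    Nmat <- as.matrix(act[, paste0("n", seq_len(K))])
    beta <- fit_linear_no_intercept(Nmat, act$hypointense_m24_ml)
    fold_r2[i] <- r_squared(drop(Nmat %*% beta), act$hypointense_m24_ml)
  }
  ok <- !is.na(fold_r2)
  list(fold_r2_mean = mean(fold_r2[ok]), fold_r2_var = stats::var(fold_r2[ok]),
       fold_r2 = fold_r2, skipped = skipped)
}

#' Fit the patient-level regression with cross-validated R^2
#'
#' Convenience wrapper: builds the active-patient design from a
#' `patient_profiles` table, fits the no-intercept model, and reports the
#' in-sample R^2 plus leave-one-patient-out summaries.
#'
#' @param profiles `patient_profiles` from [patient_cardinalities()].
#' @param K Number of clusters.
#' @return A `regression_fit`: list with `beta`, `r2_full`,
#'   `r2_loo_patient` (list: pooled, mean, var), `n_active`, `K`.
#' @export
fit_patient_model <- function(profiles, K) {
  act <- profiles[profiles$n_total > 0L, , drop = FALSE]
  Nmat <- as.matrix(act[, paste0("n", seq_len(K))])
  y <- act$hypointense_m24_ml
  beta <- fit_linear_no_intercept(Nmat, y)
  loo <- loo_patient_cv(Nmat, y)
  structure(list(beta = stats::setNames(beta, colnames(Nmat)),
                 r2_full = r_squared(drop(Nmat %*% beta), y),
                 r2_loo_patient = list(pooled = loo$pooled_r2,
                                       mean = loo$fold_r2_mean,
                                       var = loo$fold_r2_var),
                 n_active = nrow(act), K = K),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "regression_fit: K = %d, n = %d, R2 = %.3f, LOO pooled R2 = %.3f\n",
    x$K, x$n_active, x$r2_full, x$r2_loo_patient$pooled))
  cat("beta:", paste(sprintf("%s=%.3f", names(x$beta), x$beta),
                     collapse = ", "), "\n")
  invisible(x)
}
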