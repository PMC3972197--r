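# tier 2: cardinalities, no-intercept regression, leave-one-out protocols

test_that("patient cardinalities count trajectories per cluster", {
  labels <- c(1L, 1L, 3L, 2L, 2L, 2L)
  pats <- c("P1", "P1", "P1", "P2", "P2", "P3")
  prof <- patient_cardinalities(labels, pats, K = 3L)
  expect_equal(unlist(prof[prof$patient_id == "P1", c("n1", "n2", "n3")]),
               c(n1 = 2L, n2 = 0L, n3 = 1L))
  # conservation
  expect_equal(sum(prof$n_total), length(labels))
  # group assignment: severe clusters default to 2..K
  expect_equal(prof$group[prof$patient_id == "P1"], "A")
  expect_equal(prof$group[prof$patient_id == "P3"], "A")
  # restricting the severe set demotes cluster-2-only patients to group B
  prof_s3 <- patient_cardinalities(labels, pats, 3L,
                                   severe_clusters = 3L)
  expect_equal(prof_s3$group[prof_s3$patient_id == "P1"], "A")
  expect_equal(prof_s3$group[prof_s3$patient_id == "P3"], "B")

  out <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                    hypointense_m24_ml = c(2, 1, 0.5, 0.2))
  prof2 <- patient_cardinalities(labels, pats, 3L, out)
  expect_equal(prof2$group[prof2$patient_id == "P4"], "C")
  expect_equal(prof2$n_total[prof2$patient_id == "P4"], 0)
  expect_error(patient_cardinalities(labels, pats, 3L,
                                     out[out$patient_id != "P1", ]),
               "missing from outcomes")
  expect_error(patient_cardinalities(c(labels, 4L), c(pats, "P9"), 3L),
               "1..K", fixed = TRUE)
})

test_that("no-intercept least squares is exact, consistent, and minimum
           norm under rank deficiency", {
  expect_equal(fit_linear_no_intercept(matrix(1:3, ncol = 1), c(2, 4, 6)),
               2)
  set.seed(15)
  N <- matrix(rpois(60, 3), 20, 3)
  beta_star <- c(0.1, 1.5, 1.0)
  y <- drop(N %*% beta_star)
  expect_equal(fit_linear_no_intercept(N, y), beta_star, tolerance = 1e-8)

  # duplicated column: minimum-norm splits the weight, prediction unchanged
  Nd <- cbind(N, N[, 3])
  bd <- fit_linear_no_intercept(Nd, y)
  expect_equal(bd[3], bd[4])
  expect_equal(drop(Nd %*% bd), y, tolerance = 1e-8)
  expect_equal(bd[3] + bd[4], beta_star[3], tolerance = 1e-8)
  expect_error(fit_linear_no_intercept(N, y[-1]), "mismatch")
  expect_error(fit_linear_no_intercept(matrix(0, 3, 2), rep(1, 3)),
               "all zero")
})

test_that("R^2 matches its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(rep(2, 3), c(1, 2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 0.5)
  expect_error(r_squared(c(1, 2), c(3, 3)), "constant")
})

test_that("leave-one-patient-out is exact on noiseless data and fails on
           unrelated outcomes", {
  set.seed(16)
  N <- matrix(rpois(54, 3), 18, 3)
  y <- drop(N %*% c(0.1, 1.5, 1.0))
  loo <- loo_patient_cv(N, y)
  expect_equal(loo$pooled_r2, 1, tolerance = 1e-8)
  expect_equal(loo$fold_r2_mean, 1, tolerance = 1e-8)

  # y independent of N -> pooled out-of-sample R^2 <= 0 in >= 80% of seeds
  bad <- vapply(1:10, function(i) {
    set.seed(500 + i)
    Ni <- matrix(rpois(54, 3), 18, 3)
    yi <- abs(rnorm(18))
    loo_patient_cv(Ni, yi)$pooled_r2
  }, 0)
  expect_gte(mean(bad <= 0), 0.8)
  expect_error(loo_patient_cv(N[1:2, ], y[1:2]), "at least 3")
})

test_that("noisy beta recovery at study scale", {
  # 18 active patients, beta (0.1, 1.5, 1.0) ml, noise 0.1 ml
  errs <- vapply(1:10, function(i) {
    set.seed(600 + i)
    N <- cbind(rpois(18, 4) + 1, rpois(18, 0.5), rpois(18, 0.4))
    beta_star <- c(0.1, 1.5, 1.0)
    y <- pmax(drop(N %*% beta_star) + rnorm(18, 0, 0.1), 0)
    max(abs(fit_linear_no_intercept(N, y) - beta_star) / beta_star)
  }, 0)
  expect_lte(median(errs), 0.15)
})

test_that("leave-one-lesion-out tracks the patient-level protocol", {
  coh <- small_cohort(seed = 3)
  trajs <- volumes_to_trajectories(coh$volumes, 2L)
  fm <- build_feature_matrix(trajs, 2L)
  res <- loo_lesion_cv(fm, coh$outcomes, K = 3L, algorithm = "kmeans",
                       seed = 5, restarts = 5L)
  expect_true(all(is.finite(res$fold_r2) | is.na(res$fold_r2)))
  expect_equal(res$skipped + sum(!is.na(res$fold_r2)), nrow(fm$X))

  prof <- patient_cardinalities(
    kmeans_cluster(fm, 3L, 5)$labels, fm$patient_ids, 3L, coh$outcomes)
  act <- prof[prof$n_total > 0, ]
  loo_p <- loo_patient_cv(as.matrix(act[, c("n1", "n2", "n3")]),
                          act$hypointense_m24_ml)
  expect_lte(abs(res$fold_r2_mean - loo_p$fold_r2_mean), 0.1)
})

test_that("K = 1 lesion-level folds collapse to total-count regression", {
  coh <- small_cohort(seed = 4)
  trajs <- volumes_to_trajectories(coh$volumes, 2L)
  fm <- build_feature_matrix(trajs, 2L)
  res <- loo_lesion_cv(fm, coh$outcomes, K = 1L, algorithm = "kmeans",
                       seed = 2, restarts = 2L)
  # oracle: drop one trajectory by hand and regress on total counts
  prof <- patient_cardinalities(rep(1L, nrow(fm$X) - 1L),
                                fm$patient_ids[-1], 1L, coh$outcomes)
  act <- prof[prof$n_total > 0, ]
  beta <- fit_linear_no_intercept(matrix(act$n1), act$hypointense_m24_ml)
  r2 <- r_squared(act$n1 * beta, act$hypointense_m24_ml)
  expect_equal(res$fold_r2[1], r2, tolerance = 1e-9)
})

test_that("fit_patient_model assembles the full report", {
  coh <- small_cohort(seed = 5)
  trajs <- volumes_to_trajectories(coh$volumes, 2L)
  fm <- build_feature_matrix(trajs, 2L)
  prof <- patient_cardinalities(kmeans_cluster(fm, 3L, 1)$labels,
                                fm$patient_ids, 3L, coh$outcomes)
  fit <- fit_patient_model(prof, 3L)
  expect_s3_class(fit, "regression_fit")
  expect_length(fit$beta, 3L)
  expect_lte(fit$r2_full, 1)
  expect_equal(fit$n_active, sum(prof$n_total > 0))
})
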