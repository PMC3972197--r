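# Shared fixture builders. Everything is generated in code; no binary data.

# observation from explicit voxel index triples (matrix, or a flat vector
# of row-wise triples)
obs_from_coords <- function(coords, patient = "P1", t = 0L, agent = "gd",
                            label = 1L, voxel_size = c(1, 1, 1)) {
  if (!is.matrix(coords))
    coords <- matrix(as.integer(coords), ncol = 3L, byrow = TRUE)
  lesion_observation(patient, t, agent, label, coords, voxel_size)
}

# axis-aligned solid box of voxels spanning the given index ranges
obs_box <- function(is, js, ks, ...) {
  obs_from_coords(as.matrix(expand.grid(i = is, j = js, k = ks)), ...)
}

# three well-separated isotropic Gaussian blobs (centers >= 10 sd apart)
three_blobs <- function(n_per = 30L, sd = 0.5, d = 2L, seed = 1L) {
  set.seed(seed)
  centers <- rbind(rep(0, d), c(10, rep(0, d - 1L)), c(0, 10, rep(0, d - 2L)))
  X <- do.call(rbind, lapply(1:3, function(g)
    sweep(matrix(stats::rnorm(n_per * d, 0, sd), n_per, d), 2L,
          centers[g, ], "+")))
  list(X = X, labels = rep(1:3, each = n_per))
}

# the 24 proper rotations of the cubic grid, as integer matrices
grid_rotations_24 <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (s1 in c(-1, 1)) for (s2 in c(-1, 1))
    for (s3 in c(-1, 1)) {
      R <- matrix(0, 3, 3)
      R[cbind(1:3, p)] <- c(s1, s2, s3)
      if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- R
    }
  out
}

# a small but complete cohort (fast settings) for pipeline tests
small_cohort <- function(seed = 1L) {
  sample_cohort(cohort_spec(
    n_patients = 10L, group_sizes = c(A = 3L, B = 5L, C = 2L),
    c1_lambda_A = 1.5, c1_lambda_B = 2, seed = seed))
}

# map each trajectory id of a cohort run to its true pattern class
truth_classes <- function(cohort, trajectories) {
  key <- vapply(cohort$truth$lesion_classes,
                function(l) paste(l$patient_id, l$label), "")
  cls <- vapply(cohort$truth$lesion_classes, function(l) l$class, "")
  out <- vapply(trajectories, function(tr) {
    o <- tr$observations[[1L]]
    cls[match(paste(o$patient_id, o$label), key)]
  }, "")
  names(out) <- vapply(trajectories, function(tr) tr$trajectory_id, "")
  out
}

table2_path <- function() {
  system.file("extdata", "table2_patients.csv", package = "lesionpatterns")
}
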