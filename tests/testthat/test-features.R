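# shape features: centered coordinates, covariance eigenvalues, hollowness,
# feature vectors and matrices

test_that("centered_coordinate_matrix centers physical coordinates", {
  o1 <- obs_from_coords(c(3, 4, 5))
  expect_equal(centered_coordinate_matrix(o1),
               matrix(0, 1, 3), ignore_attr = TRUE)

  o2 <- obs_box(1:5, 2L, 2L)
  M <- centered_coordinate_matrix(o2)
  expect_equal(sort(M[, 1]), c(-2, -1, 0, 1, 2))
  expect_equal(max(abs(colSums(M))), 0, tolerance = 1e-12)

  o3 <- obs_from_coords(rbind(c(1, 1, 1), c(1, 1, 2)),
                        voxel_size = c(1, 1, 3))
  expect_equal(sort(centered_coordinate_matrix(o3)[, 3]), c(-1.5, 1.5))
})

test_that("covariance eigenvalues match the discrete-uniform closed form", {
  o1 <- obs_from_coords(c(3, 4, 5))
  expect_equal(covariance_eigenvalues(centered_coordinate_matrix(o1)),
               c(0, 0, 0))

  # variance of 0..n-1 at unit spacing is (n^2 - 1) / 12
  box <- obs_box(1:5, 1:3, 1L)
  ev <- covariance_eigenvalues(centered_coordinate_matrix(box))
  expect_equal(ev, c(2, 8 / 12, 0), tolerance = 1e-12)

  # m-1 normalization differs by the expected factor
  ev_s <- covariance_eigenvalues(centered_coordinate_matrix(box), "m-1")
  expect_equal(ev_s, ev * 15 / 14, tolerance = 1e-12)
})

test_that("tensor features are invariant under all 24 proper grid rotations", {
  set.seed(2)
  coords <- unique(matrix(sample(-4:4, 3 * 40, replace = TRUE), ncol = 3))
  base <- obs_from_coords(coords + 10L)
  ev0 <- covariance_eigenvalues(centered_coordinate_matrix(base))
  for (R in grid_rotations_24()) {
    rot <- coords %*% t(R)
    o <- obs_from_coords(rot + 20L)
    ev <- covariance_eigenvalues(centered_coordinate_matrix(o))
    expect_equal(ev, ev0, tolerance = 1e-9)
  }
})

test_that("isotropic scaling multiplies eigenvalues by s^2", {
  box <- obs_box(1:5, 1:3, 1:2)
  ev1 <- covariance_eigenvalues(centered_coordinate_matrix(box))
  # same mask on a 2 mm grid = isotropic scale s = 2
  box2 <- obs_box(1:5, 1:3, 1:2, voxel_size = c(2, 2, 2))
  ev2 <- covariance_eigenvalues(centered_coordinate_matrix(box2))
  expect_equal(ev2, 4 * ev1, tolerance = 1e-12)
})

test_that("voxelized solid ellipsoid eigenvalues approach (a^2, b^2, c^2)/5", {
  semi <- c(8, 5, 3)
  co <- make_ellipsoid_mask(c(20, 20, 20), semi, voxel_size = c(1, 1, 1))
  obs <- obs_from_coords(co)
  ev <- covariance_eigenvalues(centered_coordinate_matrix(obs))
  expect_equal(ev, semi^2 / 5, tolerance = 0.05)
})

test_that("hollowness separates ring from focal lesions", {
  solid <- obs_box(1:3, 1:3, 1L)
  expect_equal(hollowness_index(solid), 1)

  ring5 <- as.matrix(expand.grid(i = 1:5, j = 1:5, k = 1L))
  ring5 <- ring5[!(ring5[, 1] == 3 & ring5[, 2] == 3), ]
  expect_equal(hollowness_index(obs_from_coords(ring5)), 24 / 25)

  # one solid slice (9) + one ring slice (8 of 9)
  two <- rbind(as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1L)),
               as.matrix(expand.grid(i = 1:3, j = 1:3, k = 2L)))
  two <- two[!(two[, 1] == 2 & two[, 2] == 2 & two[, 3] == 2), ]
  expect_equal(hollowness_index(obs_from_coords(two)), 17 / 18)

  # ring H < filled H = 1, and the filled voxel set restores the square
  rng <- obs_from_coords(ring5)
  expect_lt(hollowness_index(rng), 1)
  expect_equal(nrow(fill_holes(rng)), 25L)
})

test_that("3d fill closes volumetric cavities that 2d slice fill leaves", {
  # hollow 3x3x3 shell: 2d fill closes the middle-slice hole only
  shell <- as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1:3))
  shell <- shell[!(shell[, 1] == 2 & shell[, 2] == 2 & shell[, 3] == 2), ]
  o <- obs_from_coords(shell)
  expect_equal(nrow(fill_holes(o, "slice2d")), 27L)
  expect_equal(nrow(fill_holes(o, "3d")), 27L)
  # open tube (hole through all slices): 2d fill closes it, 3d flood does not
  tube <- as.matrix(expand.grid(i = 1:3, j = 1:3, k = 1:3))
  tube <- tube[!(tube[, 1] == 2 & tube[, 2] == 2), ]
  ot <- obs_from_coords(tube)
  expect_equal(nrow(fill_holes(ot, "slice2d")), 27L)
  expect_equal(nrow(fill_holes(ot, "3d")), nrow(tube))
})

test_that("binarize_hollowness rounds to the nearest integer", {
  expect_equal(binarize_hollowness(c(1, 0.96, 0.5, 0.3)), c(1L, 1L, 1L, 0L))
  expect_error(binarize_hollowness(1.2))
})

test_that("trajectory vectors zero-fill absent blocks in a fixed layout", {
  tr <- build_trajectories(list(obs_box(1:3, 1:3, 1:3)), 2L)[[1]]
  v <- assemble_trajectory_vector(tr, 2L)
  expect_length(v, 16L)
  expect_equal(names(v)[1:4], c("gd_t0_l1", "gd_t0_l2", "gd_t0_l3",
                                "gd_t0_h"))
  expect_true(all(v[5:16] == 0))          # t1 and USPIO blocks absent
  expect_equal(unname(v[4]), 1)           # solid box, H = 1

  # volume mode: 27 voxels at 1 mm^3
  vv <- assemble_trajectory_vector(tr, 2L, mode = "volume")
  expect_equal(unname(vv), c(27, 0, 0, 0))
  expect_equal(names(vv)[1], "gd_t0_vol")

  # Gd-only variant has 8 entries
  expect_length(assemble_trajectory_vector(tr, 2L, agents = "gd"), 8L)
  expect_error(assemble_trajectory_vector(tr, 0L), "n_timepoints")
})

test_that("binary hollow mode rounds H inside the feature vector", {
  ring <- make_ring_mask(c(25, 25, 10), c(10, 10, 8), shell_fraction = 0.9,
                         voxel_size = c(1, 1, 1))
  tr <- build_trajectories(list(obs_from_coords(ring)), 2L)[[1]]
  v_cont <- assemble_trajectory_vector(tr, 2L, tensor_on = "raw")
  v_bin <- assemble_trajectory_vector(tr, 2L, hollow_mode = "binary",
                                      tensor_on = "raw")
  expect_lt(v_cont[["gd_t0_h"]], 0.5)
  expect_equal(v_bin[["gd_t0_h"]], 0)
})

test_that("feature matrix standardization and TSV round trip", {
  set.seed(5)
  obs <- lapply(1:6, function(l)
    obs_box(sample(1:30, 4), sample(1:30, 3), 1:2, label = l))
  trajs <- build_trajectories(obs, 2L)
  expect_error(build_feature_matrix(trajs[1], 2L), "at least 2")
  fm <- build_feature_matrix(trajs, 2L)
  nonconst <- setdiff(colnames(fm$X), fm$constant_cols)
  expect_equal(unname(colMeans(fm$X[, nonconst])), rep(0, length(nonconst)),
               tolerance = 1e-12)
  expect_equal(unname(apply(fm$X[, nonconst], 2, sd)),
               rep(1, length(nonconst)), tolerance = 1e-12)
  # all-zero USPIO columns are constant and flagged
  uspio_cols <- grep("uspio", colnames(fm$X), value = TRUE)
  expect_true(all(uspio_cols %in% fm$constant_cols))

  raw <- build_feature_matrix(trajs, 2L, standardize = FALSE)
  path <- file.path(tempdir(), "fm.tsv")
  write_feature_tsv(raw, path)
  back <- read_feature_tsv(path)
  expect_equal(back$X, raw$X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$patient_ids, raw$patient_ids)
  unlink(c(path, paste0(path, ".json")))
})
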