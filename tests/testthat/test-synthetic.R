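# synthetic cohort generator

test_that("voxelized sphere volume and ellipsoid anisotropy match closed
           forms", {
  # center on a voxel center so the boundary-phase error stays small
  co <- make_ellipsoid_mask(c(20.5, 20.5, 20.5), c(5, 5, 5),
                            voxel_size = c(1, 1, 1))
  expect_equal(nrow(co), 4 / 3 * pi * 125, tolerance = 0.05)

  co2 <- make_ellipsoid_mask(c(20, 20, 20), c(6, 3, 3),
                             voxel_size = c(1, 1, 1))
  ev <- covariance_eigenvalues(
    centered_coordinate_matrix(obs_from_coords(co2)))
  expect_equal(ev[1] / ev[2], 4, tolerance = 0.1)

  # rotation leaves eigenvalues unchanged within discretization error
  set.seed(21)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  co3 <- make_ellipsoid_mask(c(25, 25, 25), c(6, 3, 3), rotation = R,
                             voxel_size = c(1, 1, 1))
  ev3 <- covariance_eigenvalues(
    centered_coordinate_matrix(obs_from_coords(co3)))
  expect_equal(ev3, ev, tolerance = 0.05)
})

test_that("ring masks are hollow with H tracking the shell fraction", {
  ring <- make_ring_mask(c(25, 25, 25), c(10, 10, 8), shell_fraction = 0.6,
                         voxel_size = c(1, 1, 1))
  H <- hollowness_index(obs_from_coords(ring))
  expect_equal(H, 1 - 0.6^3, tolerance = 0.05)
  expect_lt(H, 1)

  # shell fraction -> 0 approaches a filled lesion
  thin <- make_ring_mask(c(25, 25, 25), c(10, 10, 8), shell_fraction = 0.1,
                         voxel_size = c(1, 1, 1))
  expect_gt(hollowness_index(obs_from_coords(thin)), 0.99)

  # thin-walled ring (H < 0.5) binarizes to 0
  wall <- make_ring_mask(c(25, 25, 25), c(10, 10, 8), shell_fraction = 0.9,
                         voxel_size = c(1, 1, 1))
  Hw <- hollowness_index(obs_from_coords(wall))
  expect_lt(Hw, 0.5)
  expect_equal(binarize_hollowness(Hw), 0L)

  # coarse resolution never yields an empty or non-hollow ring
  tiny <- make_ring_mask(c(6, 6, 6), c(1.4, 1.4, 1.4), 0.3,
                         voxel_size = c(1, 1, 3))
  expect_gte(nrow(tiny), 1)
})

test_that("ellipsoids exiting the volume are clipped with a warning", {
  expect_warning(
    co <- make_ellipsoid_mask(c(3, 3, 3), c(5, 5, 5),
                              voxel_size = c(1, 1, 1),
                              vol_dim = c(6L, 6L, 6L)),
    "clipped")
  expect_true(all(co <= 6))
})

test_that("pattern templates respect their class signatures", {
  spec <- cohort_spec(seed = 1)
  set.seed(33)
  classify <- function(pat) {
    agents <- vapply(pat, function(e) e$agent, "")
    ts <- vapply(pat, function(e) e$t, 0L)
    if (!"uspio" %in% agents) return("C1")
    h_gd0 <- hollowness_index(obs_from_coords(
      pat[[which(agents == "gd" & ts == 0L)]]$coords,
      voxel_size = spec$voxel_size))
    if (h_gd0 == 1) "C2" else "C3"
  }
  for (cls in c("C1", "C2", "C3")) {
    hits <- vapply(1:20, function(i)
      classify(sample_lesion_pattern(cls, spec, center = c(40, 40, 40))),
      "")
    expect_true(all(hits == cls), label = paste("templates of", cls))
  }
  # C1 features have all USPIO blocks zero; C2 has ringing USPIO over
  # focal Gd at t0
  p2 <- sample_lesion_pattern("C2", spec, center = c(40, 40, 40))
  ag <- vapply(p2, function(e) e$agent, "")
  ts <- vapply(p2, function(e) e$t, 0L)
  h_us <- hollowness_index(obs_from_coords(
    p2[[which(ag == "uspio" & ts == 0L)]]$coords,
    voxel_size = spec$voxel_size))
  expect_lt(h_us, 1)
})

test_that("default cohort matches the study design", {
  coh <- sample_cohort(cohort_spec(seed = 42))
  expect_equal(sum(coh$outcomes$group == "C"), 7L)
  expect_equal(nrow(coh$outcomes), 25L)
  expect_equal(sum(coh$outcomes$active == 0), 7L)

  # determinism: identical spec + seed reproduce the cohort exactly
  coh2 <- sample_cohort(cohort_spec(seed = 42))
  expect_identical(coh$outcomes, coh2$outcomes)
  expect_identical(coh$truth$cardinalities, coh2$truth$cardinalities)
  expect_identical(lapply(coh$volumes, function(v) v$voxels),
                   lapply(coh2$volumes, function(v) v$voxels))

  # noiseless outcomes recover beta exactly from true cardinalities
  spec0 <- cohort_spec(noise_sd = 0, seed = 7)
  coh0 <- sample_cohort(spec0)
  act <- rowSums(coh0$truth$cardinalities) > 0
  beta <- fit_linear_no_intercept(coh0$truth$cardinalities[act, ],
                                  coh0$outcomes$hypointense_m24_ml[act])
  expect_equal(unname(beta), unname(spec0$beta_true), tolerance = 1e-8)
})

test_that("enhanced-observation counts scale like the study cohort", {
  # expectation over a few seeds within +/- 30% of 103 Gd and 24 USPIO
  counts <- vapply(1:3, function(s) {
    coh <- sample_cohort(cohort_spec(seed = 800 + s))
    n_of <- function(agent) sum(vapply(coh$volumes, function(v) {
      if (v$agent != agent) return(0L)
      length(setdiff(unique(as.vector(v$voxels)), 0L))
    }, 0L))
    c(gd = n_of("gd"), uspio = n_of("uspio"))
  }, c(gd = 0, uspio = 0))
  expect_gt(mean(counts["gd", ]), 103 * 0.7)
  expect_lt(mean(counts["gd", ]), 103 * 1.3)
  expect_gt(mean(counts["uspio", ]), 24 * 0.7)
  expect_lt(mean(counts["uspio", ]), 24 * 1.3)
})

test_that("cohort export writes NIfTI volumes, outcomes and ground truth", {
  coh <- small_cohort(seed = 9)
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(coh, dir)
  niis <- list.files(dir, pattern = "\\.nii\\.gz$")
  expect_length(niis, length(coh$volumes))
  expect_true(file.exists(file.path(dir, "outcomes.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  dat <- read_cohort_dir(dir)
  expect_length(dat$volumes, length(coh$volumes))
  expect_equal(nrow(dat$outcomes), nrow(coh$outcomes))
  # voxel content survives the round trip
  v0 <- coh$volumes[[1]]
  match_v <- Filter(function(v) v$patient_id == v0$patient_id &&
                      v$time_index == v0$time_index &&
                      v$agent == v0$agent, dat$volumes)[[1]]
  expect_equal(match_v$voxels, v0$voxels)
  unlink(dir, recursive = TRUE)
})
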