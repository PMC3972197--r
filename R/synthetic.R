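# Synthetic cohort generator.
#
# Emulates the structure of the study cohort so the whole pipeline is
# testable without any imaging data: 25 patients with two baseline time
# points, ~75% filled-ellipsoid and ~25% ring-shaped lesions, three
# archetypal lesion patterns and three patient groups:
#   C1 - lesions of any size, enhancing at t0 only, generally Gd-only
#        (the common, less specific pattern);
#   C2 - medium/large lesions present at both time points with co-presence
#        of agents: focal Gd plus a ringing USPIO enhancement;
#   C3 - medium lesions mainly at t0 with both agents non-focal (ringing)
#        and of similar size.
# Group A patients carry at least one C2/C3 pattern, group B only C1
# lesions, group C none (no active lesions; excluded from fitting).
# Outcomes follow y = n . beta_true + noise, truncated at zero. beta_true
# and the size classes are free parameters of the generator (documented in
# the methods vignette), not values from any real cohort.

#' Cohort specification
#'
#' Defaults state the study-scale world: 25 patients split 5/13/7 into
#' groups A/B/C, two time points, lesion counts tuned to ~103 Gd and ~24
#' USPIO enhanced observations in expectation, 1 x 1 x 3 mm voxels (axial
#' 2D acquisitions), size classes small 2-4 / medium 5-8 / large 9-15 mm
#' semi-major axis.
#'
#' @param n_patients Total patients.
#' @param n_timepoints Baseline time points N.
#' @param group_sizes Named integer vector, patients per group A/B/C.
#' @param voxel_size Length-3 mm.
#' @param size_classes List of `c(lo, hi)` semi-major-axis ranges (mm).
#' @param ring_fraction Probability that a C1 Gd lesion is ring-shaped
#'   (C2 USPIO and C3 lesions are always rings), so ~25% of lesions are
#'   rings overall.
#' @param c1_lambda_A,c1_lambda_B Poisson means for extra C1 lesions (each
#'   active patient has at least one C1).
#' @param beta_true Outcome ml per lesion for (C1, C2, C3).
#' @param noise_sd Outcome noise SD in ml.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 25L, n_timepoints = 2L,
                        group_sizes = c(A = 5L, B = 13L, C = 7L),
                        voxel_size = c(1, 1, 3),
                        size_classes = list(small = c(2, 4),
                                            medium = c(5, 8),
                                            large = c(9, 15)),
                        ring_fraction = 0.25,
                        c1_lambda_A = 3.5, c1_lambda_B = 4,
                        beta_true = c(C1 = 0.1, C2 = 1.5, C3 = 1.0),
                        noise_sd = 0.1, seed = 1L) {
  if (sum(group_sizes) != n_patients)
    stop("group sizes must sum to n_patients")
  if (group_sizes[["A"]] < 1L)
    stop("group A needs at least one patient (C2/C3 carriers)")
  stopifnot(n_timepoints >= 1L, all(voxel_size > 0),
            ring_fraction >= 0, ring_fraction <= 1, noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Voxelize a solid or ring ellipsoid
#'
#' Selects the voxels whose mm-centers `((i,j,k) - 0.5) * voxel_size` lie
#' inside the rotated ellipsoid; for `shape = "ring"` a concentric inner
#' ellipsoid scaled by `shell_fraction` is removed (if the inner region
#' captures no voxel at the given resolution, the voxel nearest the center
#' is removed instead so that H < 1 still holds). If no voxel center falls
#' inside a very small ellipsoid, the nearest voxel is used so the mask is
#' never empty; masks exceeding `vol_dim` are clipped with a warning.
#'
#' @param center Ellipsoid center in mm.
#' @param semi_axes Length-3 semi-axes in mm.
#' @param rotation 3x3 rotation matrix (columns = ellipsoid axes), or
#'   `NULL` for axis-aligned.
#' @param voxel_size Length-3 mm.
#' @param shape `"solid"` or `"ring"`.
#' @param shell_fraction Inner/outer scale for rings, in (0, 1).
#' @param vol_dim Optional length-3 integer bounds for clipping.
#' @return Integer m x 3 matrix of (i, j, k) voxel indices (1-based).
#' @export
make_ellipsoid_mask <- function(center, semi_axes, rotation = NULL,
                                voxel_size = c(1, 1, 1),
                                shape = c("solid", "ring"),
                                shell_fraction = 0.6, vol_dim = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L,
            all(semi_axes > 0))
  if (is.null(rotation)) rotation <- diag(3)
  r <- max(semi_axes)
  lo <- pmax(1L, as.integer(floor((center - r) / voxel_size + 0.5)))
  hi <- as.integer(ceiling((center + r) / voxel_size + 0.5))
  if (!is.null(vol_dim)) {
    if (any(hi > vol_dim) || any((center - r) < 0)) {
      warning("ellipsoid exits volume bounds; clipped")
      hi <- pmin(hi, vol_dim)
    }
  }
  grid <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  mm <- sweep(grid - 0.5, 2L, voxel_size, "*")
  u <- sweep(mm, 2L, center, "-") %*% rotation  # coords in ellipsoid frame
  q_out <- rowSums(sweep(u, 2L, semi_axes, "/")^2)
  inside <- q_out <= 1
  if (!any(inside)) {
    # degenerate at coarse resolution: take the voxel nearest the center
    inside[which.min(rowSums(sweep(mm, 2L, center, "-")^2))] <- TRUE
    return(grid[inside, , drop = FALSE])
  }
  if (shape == "ring") {
    stopifnot(shell_fraction > 0, shell_fraction < 1)
    q_in <- rowSums(sweep(u, 2L, shell_fraction * semi_axes, "/")^2)
    hollow <- inside & q_in <= 1
    if (!any(hollow)) {
      cand <- which(inside)
      hollow_idx <- cand[which.min(rowSums(sweep(mm[cand, , drop = FALSE],
                                                 2L, center, "-")^2))]
      hollow <- logical(length(inside))
      hollow[hollow_idx] <- TRUE
    }
    if (all(inside == hollow))  # never empty the mask entirely
      hollow[which(inside)[1L]] <- FALSE
    inside <- inside & !hollow
  }
  grid[inside, , drop = FALSE]
}

#' @rdname make_ellipsoid_mask
#' @export
make_ring_mask <- function(center, semi_axes, shell_fraction = 0.6,
                           rotation = NULL, voxel_size = c(1, 1, 1),
                           vol_dim = NULL) {
  make_ellipsoid_mask(center, semi_axes, rotation, voxel_size,
                      shape = "ring", shell_fraction = shell_fraction,
                      vol_dim = vol_dim)
}

# Semi-axes with a truncated log-normal semi-major axis over [lo, hi] mm.
# Enhancing MS lesion sizes form a right-skewed continuum (typical lesions
# ~8 mm diameter, i.e. ~4 mm semi-axis; 2-3 cm lesions exist but are rare),
# not discrete strata: the small/medium/large vocabulary in
# spec$size_classes is descriptive. Sampling is by inverse-CDF so
# truncation is exact and cheap.
sample_semi_axes <- function(spec, lo, hi,
                             meanlog = log(4), sdlog = 0.5) {
  p <- stats::runif(1, stats::plnorm(lo, meanlog, sdlog),
                    stats::plnorm(hi, meanlog, sdlog))
  a <- stats::qlnorm(p, meanlog, sdlog)
  axes <- c(a, a * stats::runif(2, 0.55, 0.95))
  pmax(axes, max(spec$voxel_size) / 2)
}

size_class_of <- function(spec, a) {
  brk <- vapply(spec$size_classes, max, 0)
  names(spec$size_classes)[min(which(a <= brk + 1e-9), length(brk))]
}

#' Sample one archetypal lesion pattern
#'
#' Draws the per-(time point, agent) mask descriptors for one lesion of
#' class C1, C2 or C3 (see the package-level description of the patterns),
#' with randomized size, orientation and a small center jitter that
#' preserves cross-time/agent overlap.
#'
#' @param class `"C1"`, `"C2"` or `"C3"`.
#' @param spec A [cohort_spec()].
#' @param center Lesion center in mm.
#' @return List of entries `list(t, agent, coords)` (class
#'   `lesion_pattern`), with attribute `class`.
#' @export
sample_lesion_pattern <- function(class = c("C1", "C2", "C3"), spec,
                                  center = c(30, 30, 30)) {
  class <- match.arg(class)
  vs <- spec$voxel_size
  rot <- random_rotation()
  jit <- function() center + stats::runif(3, -1, 1)
  out <- list()
  add <- function(t, agent, semi, shape, shell = 0.6) {
    out[[length(out) + 1L]] <<- list(
      t = t, agent = agent,
      coords = make_ellipsoid_mask(jit(), semi, rot, vs, shape = shape,
                                   shell_fraction = shell))
  }
  lo_all <- min(vapply(spec$size_classes, min, 0))
  hi_all <- max(vapply(spec$size_classes, max, 0))
  med <- spec$size_classes$medium
  if (class == "C1") {
    # any size (small through large), t0 only, generally Gd-only
    semi <- sample_semi_axes(spec, lo_all, hi_all)
    shape <- if (stats::runif(1) < spec$ring_fraction) "ring" else "solid"
    add(0L, "gd", semi, shape, shell = stats::runif(1, 0.3, 0.8))
  } else if (class == "C2") {
    # medium-to-large, persistent, focal Gd + ringing USPIO around it;
    # severe patterns are archetypes: template-tight parameter ranges
    semi <- sample_semi_axes(spec, med[2], (med[2] + hi_all) / 2)
    shell <- stats::runif(1, 0.45, 0.65)
    add(0L, "gd", semi, "solid")
    add(0L, "uspio", semi * stats::runif(1, 1.05, 1.15), "ring", shell)
    if (spec$n_timepoints > 1L) {
      s1 <- stats::runif(1, 0.85, 1.0)
      add(1L, "gd", semi * s1, "solid")
      add(1L, "uspio", semi * s1 * stats::runif(1, 1.05, 1.15), "ring",
          shell)
    }
  } else {
    # medium, mainly t0, both agents ringing and approximately same size
    semi <- sample_semi_axes(spec, med[1], med[2])
    shell <- stats::runif(1, 0.45, 0.65)
    add(0L, "gd", semi, "ring", shell)
    add(0L, "uspio", semi * stats::runif(1, 0.95, 1.05), "ring", shell)
    if (spec$n_timepoints > 1L && stats::runif(1) < 0.2) {
      s1 <- stats::runif(1, 0.75, 0.9)
      add(1L, "gd", semi * s1, "ring", shell)
      add(1L, "uspio", semi * s1, "ring", shell)
    }
  }
  structure(out, class = "lesion_pattern", pattern_class = class)
}

#' Generate a full synthetic cohort
#'
#' Draws per-patient lesion counts by group, places lesions on a
#' non-overlapping lattice, voxelizes every (time point, agent) mask into
#' labeled volumes, and generates outcomes
#' `y_i = n_i . beta_true + eps, eps ~ N(0, noise_sd^2)`, truncated at 0
#' (group C patients get pure truncated noise). Fully deterministic given
#' the spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with `volumes` (list of
#'   [mask_volume()], one per patient/time/agent with at least the t0 Gd
#'   volume present for active patients), `outcomes` (data.frame
#'   `patient_id`, `hypointense_m24_ml`, `tll_m24_ml`, `active`, `group`),
#'   `truth` (per-lesion classes, per-patient cardinalities, `beta_true`,
#'   noiseless outcomes), `spec`.
#' @export
sample_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  groups <- rep(c("A", "B", "C"), times = spec$group_sizes[c("A", "B", "C")])
  pids <- sprintf("P%02d", seq_len(spec$n_patients))
  classes <- c("C1", "C2", "C3")
  card <- matrix(0L, spec$n_patients, 3L,
                 dimnames = list(pids, classes))
  lesion_classes <- list()
  volumes <- list()
  # slot spacing leaves room for the largest lesion, its 1.2x USPIO ring
  # and the 1 mm center jitter, so distinct lesions can never touch
  spacing <- 2 * (max(vapply(spec$size_classes, max, 0)) * 1.2 + 1) + 4
  for (p in seq_len(spec$n_patients)) {
    pid <- pids[p]
    n_by_class <- c(C1 = 0L, C2 = 0L, C3 = 0L)
    if (groups[p] == "A") {
      n_by_class["C1"] <- 1L + stats::rpois(1, spec$c1_lambda_A)
      n_by_class["C2"] <- 1L + stats::rbinom(1, 1, 0.5)
      n_by_class["C3"] <- stats::rbinom(1, 1, 0.7) + stats::rbinom(1, 1, 0.3)
    } else if (groups[p] == "B") {
      n_by_class["C1"] <- 1L + stats::rpois(1, spec$c1_lambda_B)
    }
    card[p, ] <- n_by_class
    n_lesions <- sum(n_by_class)
    if (n_lesions == 0L) next
    # lattice of lesion slots, cube-ish
    n_side <- ceiling(n_lesions^(1 / 3))
    slots <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                   z = seq_len(ceiling(n_lesions / n_side^2))))
    vol_dim <- as.integer(ceiling(
      (apply(slots, 2L, max) * spacing) / spec$voxel_size))
    arr <- list()  # one labeled array per (t, agent)
    lesion_list <- rep(classes, times = n_by_class)
    for (li in seq_len(n_lesions)) {
      cls <- lesion_list[li]
      ctr <- (slots[li, ] - 0.5) * spacing
      pat <- sample_lesion_pattern(cls, spec, center = ctr)
      lesion_classes[[length(lesion_classes) + 1L]] <-
        list(patient_id = pid, label = li, class = cls)
      for (entry in pat) {
        key <- sprintf("t%d_%s", entry$t, entry$agent)
        if (is.null(arr[[key]])) arr[[key]] <- array(0L, vol_dim)
        co <- entry$coords
        ok <- co[, 1] <= vol_dim[1] & co[, 2] <= vol_dim[2] &
              co[, 3] <= vol_dim[3]
        arr[[key]][co[ok, , drop = FALSE]] <- li
      }
    }
    for (key in names(arr)) {
      t <- as.integer(sub("^t(\\d+)_.*$", "\\1", key))
      agent <- sub("^t\\d+_", "", key)
      volumes[[paste(pid, key, sep = "_")]] <-
        mask_volume(arr[[key]], spec$voxel_size, pid, t, agent)
    }
  }
  y_true <- drop(card %*% spec$beta_true)
  y <- pmax(y_true + stats::rnorm(spec$n_patients, 0, spec$noise_sd), 0)
  tll <- pmax(y * stats::runif(spec$n_patients, 1.5, 3.5) +
                abs(stats::rnorm(spec$n_patients, 0.5, 0.3)), 0)
  outcomes <- data.frame(patient_id = pids,
                         hypointense_m24_ml = y,
                         tll_m24_ml = tll,
                         active = as.integer(rowSums(card) > 0L),
                         group = groups,
                         stringsAsFactors = FALSE)
  structure(list(volumes = volumes, outcomes = outcomes,
                 truth = list(lesion_classes = lesion_classes,
                              cardinalities = card,
                              beta_true = spec$beta_true,
                              y_noiseless = y_true),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic_cohort: %d patients (%s), %d labeled volumes, %d lesions\n",
    x$spec$n_patients,
    paste(sprintf("%s=%d", names(table(x$outcomes$group)),
                  table(x$outcomes$group)), collapse = "/"),
    length(x$volumes), length(x$truth$lesion_classes)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits one NIfTI volume per (patient, time, agent) named
#' `<patient>_<t>_<agent>.nii.gz`, the outcome CSV and a ground-truth JSON.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$volumes)
    write_nifti(v$voxels,
                file.path(dir, sprintf("%s_%d_%s.nii.gz", v$patient_id,
                                       v$time_index, v$agent)),
                v$voxel_size)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  truth$cardinalities <- as.data.frame(truth$cardinalities)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
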