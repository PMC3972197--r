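# Tensor-like shape features and hollowness.
#
# Each lesion observation is summarized by the eigenvalues of the covariance
# of its voxel coordinates in mm (a rotation-invariant size/anisotropy
# descriptor: the eigenvectors are discarded) plus a hollowness index
# H = A / A_fill that separates ring-enhancing (H < 1) from focal (H = 1)
# lesions. Ring lesions are represented "as filled" for the tensor: the
# covariance is computed on the hole-filled voxel set while H records the
# hollowness.

#' Voxel coordinates in mm
#'
#' Converts 1-based voxel indices to physical coordinates of voxel centers,
#' `(idx - 0.5) * voxel_size`, so anisotropic acquisitions (3 mm slices) do
#' not distort the geometry.
#'
#' @param obs A [lesion_observation()].
#' @param coords Optional coordinate matrix overriding `obs$coords` (used for
#'   hole-filled voxel sets).
#' @return m x 3 numeric matrix, mm.
#' @keywords internal
coords_mm <- function(obs, coords = obs$coords) {
  sweep(coords - 0.5, 2L, obs$voxel_size, "*")
}

#' Centered coordinate data matrix
#'
#' The m x 3 matrix of voxel coordinates (mm) with the per-axis means
#' subtracted; its covariance carries the lesion's size and anisotropy.
#'
#' @inheritParams coords_mm
#' @return m x 3 numeric matrix with zero column sums.
#' @export
centered_coordinate_matrix <- function(obs, coords = obs$coords) {
  x <- coords_mm(obs, coords)
  sweep(x, 2L, colMeans(x), "-")
}

#' Eigenvalues of the coordinate covariance
#'
#' Decomposes `C = M'M / m` (population normalization by default; `m - 1`
#' available) and returns the eigenvalues sorted in decreasing order, which
#' makes the descriptor orientation independent. Tiny negative values from
#' floating point are clamped to 0.
#'
#' @param M Centered m x 3 matrix from [centered_coordinate_matrix()].
#' @param divisor `"m"` (population covariance) or `"m-1"`.
#' @return Numeric length 3, `lambda1 >= lambda2 >= lambda3 >= 0`, in mm^2.
#' @export
covariance_eigenvalues <- function(M, divisor = c("m", "m-1")) {
  divisor <- match.arg(divisor)
  m <- nrow(M)
  den <- if (divisor == "m") m else max(m - 1L, 1L)
  C <- crossprod(M) / den
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  pmax(sort(ev, decreasing = TRUE), 0)
}

# Fill 2D holes in a logical matrix: background cells (FALSE) not 4-connected
# to the matrix border become foreground. Iterative propagation of the
# border-connected background; slices are small so this is cheap.
fill_holes_matrix <- function(sl) {
  bg <- !sl
  reach <- matrix(FALSE, nrow(sl), ncol(sl))
  reach[1, ] <- bg[1, ]; reach[nrow(sl), ] <- bg[nrow(sl), ]
  reach[, 1] <- bg[, 1]; reach[, ncol(sl)] <- bg[, ncol(sl)]
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-nrow(sl), ]
    grown[-nrow(sl), ] <- grown[-nrow(sl), ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -ncol(sl)]
    grown[, -ncol(sl)] <- grown[, -ncol(sl)] | reach[, -1]
    grown <- grown & bg
    if (identical(grown, reach)) break
    reach <- grown
  }
  sl | (bg & !reach)
}

#' Hole-filled voxel set of an observation
#'
#' Fills interior holes of the lesion mask. The default fills independently
#' on each axial (constant-k) slice, matching the 2D axial acquisitions the
#' area-based hollowness refers to; `"3d"` fills volumetric cavities using
#' 6-connected background flooding.
#'
#' @param obs A [lesion_observation()].
#' @param mode `"slice2d"` (default) or `"3d"`.
#' @return Integer matrix of (i, j, k) voxel indices including filled holes.
#' @export
fill_holes <- function(obs, mode = c("slice2d", "3d")) {
  mode <- match.arg(mode)
  co <- obs$coords
  # work in a padded local bounding box so the border is always background
  lo <- apply(co, 2L, min) - 1L
  hi <- apply(co, 2L, max) + 1L
  dm <- hi - lo + 1L
  local <- sweep(co, 2L, lo - 1L, "-")
  if (mode == "slice2d") {
    out <- vector("list", dm[3])
    for (kz in sort(unique(local[, 3]))) {
      sel <- local[, 3] == kz
      sl <- matrix(FALSE, dm[1], dm[2])
      sl[local[sel, 1:2, drop = FALSE]] <- TRUE
      filled <- fill_holes_matrix(sl)
      w <- which(filled, arr.ind = TRUE)
      out[[kz]] <- cbind(w, kz)
    }
    fill_local <- do.call(rbind, out)
  } else {
    vol <- array(FALSE, dm)
    vol[local] <- TRUE
    bg <- !vol
    reach <- array(FALSE, dm)
    reach[1, , ] <- bg[1, , ]; reach[dm[1], , ] <- bg[dm[1], , ]
    reach[, 1, ] <- reach[, 1, ] | bg[, 1, ]
    reach[, dm[2], ] <- reach[, dm[2], ] | bg[, dm[2], ]
    reach[, , 1] <- reach[, , 1] | bg[, , 1]
    reach[, , dm[3]] <- reach[, , dm[3]] | bg[, , dm[3]]
    repeat {
      grown <- reach
      grown[-1, , ] <- grown[-1, , ] | reach[-dm[1], , ]
      grown[-dm[1], , ] <- grown[-dm[1], , ] | reach[-1, , ]
      grown[, -1, ] <- grown[, -1, ] | reach[, -dm[2], ]
      grown[, -dm[2], ] <- grown[, -dm[2], ] | reach[, -1, ]
      grown[, , -1] <- grown[, , -1] | reach[, , -dm[3]]
      grown[, , -dm[3]] <- grown[, , -dm[3]] | reach[, , -1]
      grown <- grown & bg
      if (identical(grown, reach)) break
      reach <- grown
    }
    fill_local <- which(vol | (bg & !reach), arr.ind = TRUE)
  }
  sweep(fill_local, 2L, lo - 1L, "+")
}

#' Hollowness index H = A / A_fill
#'
#' Ratio of the delineated lesion area to the same area with holes filled
#' (per axial slice by default), summed over slices. H = 1 for a focal
#' (simply connected) lesion and < 1 in the presence of a hole, as for
#' ring-enhancing lesions.
#'
#' @inheritParams fill_holes
#' @return Numeric scalar in (0, 1\].
#' @export
hollowness_index <- function(obs, mode = c("slice2d", "3d")) {
  nrow(obs$coords) / nrow(fill_holes(obs, mode))
}

#' Round hollowness to a binary focal/ring indicator
#'
#' Nearest-integer rounding: `H >= 0.5` maps to 1 (focal-like), otherwise 0
#' (markedly hollow / ring-like).
#'
#' @param H Hollowness values in (0, 1\].
#' @return Integer vector of 0/1.
#' @export
binarize_hollowness <- function(H) {
  stopifnot(all(H > 0 & H <= 1))
  as.integer(H >= 0.5)
}

#' Shape features of one observation
#'
#' @inheritParams fill_holes
#' @param tensor_on `"filled"` (default: covariance on the hole-filled voxel
#'   set, ring lesions represented as filled) or `"raw"`.
#' @param divisor Covariance normalization, see [covariance_eigenvalues()].
#' @return List with `eigenvalues` (mm^2), `hollowness`, `volume` (mm^3).
#' @export
observation_shape_features <- function(obs, tensor_on = c("filled", "raw"),
                                       mode = c("slice2d", "3d"),
                                       divisor = c("m", "m-1")) {
  tensor_on <- match.arg(tensor_on)
  mode <- match.arg(mode)
  filled <- fill_holes(obs, mode)
  H <- nrow(obs$coords) / nrow(filled)
  co <- if (tensor_on == "filled") filled else obs$coords
  ev <- covariance_eigenvalues(centered_coordinate_matrix(obs, co),
                               match.arg(divisor))
  list(eigenvalues = ev, hollowness = H,
       volume = nrow(obs$coords) * prod(obs$voxel_size))
}

#' Assemble a trajectory's feature vector
#'
#' Tensor mode stacks, per contrast agent and time point, the block
#' `(lambda1, lambda2, lambda3, H)`; volume mode uses the scalar lesion
#' volume in mm^3. All Gd blocks (t = 0..N-1) come first, then all USPIO
#' blocks; blocks with no observation are exactly zero, representing absent
#' enhancement.
#'
#' @param traj A `lesion_trajectory`.
#' @param n_timepoints Number of time points N.
#' @param mode `"tensor"` or `"volume"`.
#' @param hollow_mode `"continuous"` or `"binary"` (H rounded to 0/1).
#' @param agents Agents to include, default both (`c("gd", "uspio")`);
#'   `"gd"` gives the Gd-only variant.
#' @param ... Passed to [observation_shape_features()].
#' @return Named numeric vector of length `4 * N * length(agents)` (tensor)
#'   or `N * length(agents)` (volume).
#' @export
assemble_trajectory_vector <- function(traj, n_timepoints,
                                       mode = c("tensor", "volume"),
                                       hollow_mode = c("continuous", "binary"),
                                       agents = c("gd", "uspio"), ...) {
  mode <- match.arg(mode)
  hollow_mode <- match.arg(hollow_mode)
  tmax <- max(vapply(traj$observations, function(o) o$time_index, 0L))
  if (tmax >= n_timepoints)
    stop("trajectory has time_index ", tmax, " >= n_timepoints")
  blocks <- list()
  for (agent in agents) {
    for (t in 0:(n_timepoints - 1L)) {
      key <- sprintf("t%d_%s", t, agent)
      prefix <- sprintf("%s_t%d", agent, t)
      obs <- traj$observations[[key]]
      if (mode == "tensor") {
        v <- c(0, 0, 0, 0)
        if (!is.null(obs)) {
          sf <- observation_shape_features(obs, ...)
          h <- if (hollow_mode == "binary")
            binarize_hollowness(sf$hollowness) else sf$hollowness
          v <- c(sf$eigenvalues, h)
        }
        names(v) <- paste0(prefix, "_", c("l1", "l2", "l3", "h"))
      } else {
        v <- if (is.null(obs)) 0
             else nrow(obs$coords) * prod(obs$voxel_size)
        names(v) <- paste0(prefix, "_vol")
      }
      blocks[[key]] <- v
    }
  }
  v <- unlist(blocks, use.names = FALSE)
  names(v) <- unlist(lapply(blocks, names), use.names = FALSE)
  v
}

#' Build the trajectory feature matrix
#'
#' Stacks trajectory feature vectors in stable trajectory-id order and
#' optionally standardizes columns (center, unit variance; constant columns
#' are centered only and flagged). The eigenvalues (mm^2, up to hundreds)
#' and H (at most 1) live on incommensurate scales, so standardization
#' defaults on for clustering.
#'
#' @param trajectories List of `lesion_trajectory`.
#' @param n_timepoints Number of time points N.
#' @param standardize Center/scale columns (default `TRUE`).
#' @inheritParams assemble_trajectory_vector
#' @return A `feature_matrix` object: list with `X` (numeric matrix, rownames
#'   = trajectory ids), `row_ids`, `standardized`, `center`, `scale`,
#'   `constant_cols`, `patient_ids`.
#' @export
build_feature_matrix <- function(trajectories, n_timepoints,
                                 mode = c("tensor", "volume"),
                                 hollow_mode = c("continuous", "binary"),
                                 agents = c("gd", "uspio"),
                                 standardize = TRUE, ...) {
  if (length(trajectories) < 2L)
    stop("need at least 2 trajectories to build a feature matrix")
  ids <- vapply(trajectories, function(tr) tr$trajectory_id, "")
  ord <- order(ids)
  trajectories <- trajectories[ord]
  ids <- ids[ord]
  rows <- lapply(trajectories, assemble_trajectory_vector,
                 n_timepoints = n_timepoints, mode = mode,
                 hollow_mode = hollow_mode, agents = agents, ...)
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  const <- apply(X, 2L, function(col) stats::var(col) == 0)
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[const] <- 1  # constant columns: centered to 0, left unscaled
    X <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  }
  structure(list(X = X, row_ids = ids, standardized = standardize,
                 center = ctr, scale = scl, constant_cols = names(const)[const],
                 patient_ids = vapply(trajectories,
                                      function(tr) tr$patient_id, "")),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d trajectories x %d features%s\n",
              nrow(x$X), ncol(x$X),
              if (x$standardized) " (standardized)" else ""))
  if (length(x$constant_cols) > 0L)
    cat("constant columns:", paste(x$constant_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Export / import a feature matrix as TSV with a JSON sidecar
#'
#' The TSV has a `trajectory_id` column followed by the feature columns; the
#' sidecar (`<path>.json`) stores standardization parameters and patient ids
#' so a run can be reproduced from the exported table alone.
#'
#' @param fm A `feature_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fm, path) {
  df <- data.frame(trajectory_id = fm$row_ids, fm$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(standardized = fm$standardized, center = fm$center,
               scale = fm$scale, constant_cols = fm$constant_cols,
               patient_ids = fm$patient_ids)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @param path TSV path written by [write_feature_tsv()].
#' @return For `read_feature_tsv`, a `feature_matrix`.
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  rownames(X) <- df$trajectory_id
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list(standardized = FALSE, center = rep(0, ncol(X)),
                    scale = rep(1, ncol(X)), constant_cols = character(),
                    patient_ids = rep(NA_character_, nrow(X)))
  structure(list(X = X, row_ids = df$trajectory_id,
                 standardized = isTRUE(meta$standardized),
                 center = meta$center, scale = meta$scale,
                 constant_cols = meta$constant_cols,
                 patient_ids = meta$patient_ids),
            class = "feature_matrix")
}
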