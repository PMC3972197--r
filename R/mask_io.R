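# Labeled lesion-mask containers and observation extraction.
#
# A mask volume is one integer-labeled 3D image for one (patient, time point,
# contrast agent); label 0 is background and each positive label is one
# manually delineated lesion. A lesion observation is the voxel set of one
# label, carried as 1-based (i, j, k) indices plus the voxel size in mm so
# that all geometry downstream can work in physical coordinates (the study
# mixes 1x1x3 mm 2D acquisitions with finer 3D ones).

AGENTS <- c("gd", "uspio")

#' Construct a mask volume
#'
#' @param voxels 3D array of non-negative integer labels (0 = background).
#' @param voxel_size Length-3 positive numeric, voxel edge lengths in mm.
#' @param patient_id Patient identifier (character scalar).
#' @param time_index 0-based time-point index.
#' @param agent `"gd"` or `"uspio"`.
#' @return A `mask_volume` object.
#' @export
mask_volume <- function(voxels, voxel_size, patient_id, time_index, agent) {
  agent <- match.arg(tolower(agent), AGENTS)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (any(voxels < 0) || any(voxels != round(voxels)))
    stop("labels must be non-negative integers")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths in mm")
  structure(list(voxels = voxels,
                 voxel_size = as.numeric(voxel_size),
                 patient_id = as.character(patient_id),
                 time_index = as.integer(time_index),
                 agent = agent),
            class = "mask_volume")
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("mask_volume %s t%d %s: %s voxels, %d lesion label(s), %s mm\n",
              x$patient_id, x$time_index, x$agent,
              paste(dim(x$voxels), collapse = "x"),
              length(setdiff(unique(as.vector(x$voxels)), 0L)),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

#' Construct a lesion observation
#'
#' @param patient_id,time_index,agent As in [mask_volume()].
#' @param label Positive integer lesion label.
#' @param coords m x 3 integer matrix of (i, j, k) voxel indices (1-based).
#' @param voxel_size Length-3 numeric, mm.
#' @return A `lesion_observation` object.
#' @export
lesion_observation <- function(patient_id, time_index, agent, label, coords,
                               voxel_size) {
  coords <- matrix(as.integer(coords), ncol = 3L)
  if (nrow(coords) < 1L) stop("observation must contain at least one voxel")
  if (anyDuplicated(coords)) stop("duplicate voxel coordinates")
  structure(list(patient_id = as.character(patient_id),
                 time_index = as.integer(time_index),
                 agent = match.arg(tolower(agent), AGENTS),
                 label = as.integer(label),
                 coords = coords,
                 voxel_size = as.numeric(voxel_size)),
            class = "lesion_observation")
}

#' @export
print.lesion_observation <- function(x, ...) {
  cat(sprintf("lesion_observation %s t%d %s label %d: m = %d voxels\n",
              x$patient_id, x$time_index, x$agent, x$label, nrow(x$coords)))
  invisible(x)
}

#' Load a labeled mask volume from disk
#'
#' Reads a NIfTI-1 labeled volume. When `binary = TRUE` the volume is treated
#' as a binary mask and distinct lesions are recovered by 26-connected
#' component labeling (fallback for masks that were not exported with one
#' label per lesion).
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @inheritParams mask_volume
#' @param binary Label connected components of `voxels > 0` instead of
#'   trusting the stored labels.
#' @return A [mask_volume()].
#' @export
load_mask_volume <- function(path, patient_id, time_index, agent,
                             binary = FALSE) {
  img <- read_nifti(path)
  vox <- img$data
  if (binary) vox <- label_components_26(vox > 0)
  mask_volume(vox, img$voxel_size, patient_id, time_index, agent)
}

#' Label 26-connected components of a binary 3D mask
#'
#' Two foreground voxels are connected when they differ by at most one step
#' along each axis. Components are numbered 1.. in order of their smallest
#' linear index.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @return Integer 3D array of component labels, 0 = background.
#' @export
label_components_26 <- function(mask) {
  dm <- dim(mask)
  stopifnot(length(dm) == 3L)
  mask <- array(as.logical(mask), dm)
  lab <- array(0L, dm)
  idx_fg <- which(mask)
  if (length(idx_fg) == 0L) return(lab)
  # precompute neighbor offsets in linear-index space, used with bounds checks
  ar <- arrayInd(idx_fg, dm)
  key <- paste(ar[, 1], ar[, 2], ar[, 3])
  pos <- new.env(hash = TRUE, size = length(idx_fg))
  for (r in seq_along(key)) assign(key[r], r, envir = pos)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  comp <- integer(length(idx_fg))
  cur <- 0L
  for (r in seq_along(idx_fg)) {
    if (comp[r] != 0L) next
    cur <- cur + 1L
    queue <- r
    comp[r] <- cur
    while (length(queue) > 0L) {
      q <- queue[[1L]]
      queue <- queue[-1L]
      nb <- sweep(off, 2L, ar[q, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
            nb[, 2] >= 1 & nb[, 2] <= dm[2] &
            nb[, 3] >= 1 & nb[, 3] <= dm[3]
      nb <- nb[ok, , drop = FALSE]
      nk <- paste(nb[, 1], nb[, 2], nb[, 3])
      for (k in nk) {
        j <- pos[[k]]
        if (!is.null(j) && comp[j] == 0L) {
          comp[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab[idx_fg] <- comp
  lab
}

#' Extract one observation per lesion label
#'
#' Collects, for every distinct nonzero label in the volume, the voxel
#' coordinates carrying that label. Labels are reported in ascending order.
#'
#' @param volume A [mask_volume()].
#' @return List of [lesion_observation()] (empty for an all-zero mask).
#' @export
extract_observations <- function(volume) {
  stopifnot(inherits(volume, "mask_volume"))
  labs <- sort(setdiff(unique(as.vector(volume$voxels)), 0L))
  lapply(labs, function(l) {
    idx <- which(volume$voxels == l)
    lesion_observation(volume$patient_id, volume$time_index, volume$agent,
                       l, arrayInd(idx, dim(volume$voxels)),
                       volume$voxel_size)
  })
}

#' Read lesion observations from the CSV voxel-list dialect
#'
#' The fixture dialect is a plain CSV with columns
#' `patient,t,agent,label,i,j,k`, one row per voxel. Voxel size is not part
#' of the dialect and is supplied by the caller.
#'
#' @param path CSV path.
#' @param voxel_size Length-3 numeric, mm (applied to all observations).
#' @return List of [lesion_observation()].
#' @export
read_voxel_csv <- function(path, voxel_size = c(1, 1, 1)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "t", "agent", "label", "i", "j", "k")
  if (!all(need %in% names(df)))
    stop("voxel CSV must have columns ", paste(need, collapse = ","))
  groups <- split(df, list(df$patient, df$t, df$agent, df$label), drop = TRUE)
  obs <- lapply(groups, function(g)
    lesion_observation(g$patient[1], g$t[1], g$agent[1], g$label[1],
                       cbind(g$i, g$j, g$k), voxel_size))
  names(obs) <- NULL
  ord <- order(vapply(obs, function(o) o$patient_id, ""),
               vapply(obs, function(o) o$time_index, 0L),
               vapply(obs, function(o) o$agent, ""),
               vapply(obs, function(o) o$label, 0L))
  obs[ord]
}

#' Write lesion observations to the CSV voxel-list dialect
#'
#' @param observations List of [lesion_observation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_voxel_csv <- function(observations, path) {
  rows <- lapply(observations, function(o)
    data.frame(patient = o$patient_id, t = o$time_index, agent = o$agent,
               label = o$label, i = o$coords[, 1], j = o$coords[, 2],
               k = o$coords[, 3]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
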