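# Lesion correspondence by spatial overlap.
#
# Masks are assumed co-registered to the first time point upstream; a lesion
# observed at two time points (or under the two contrast agents) is declared
# the same lesion when its voxel sets overlap. When one observation overlaps
# several candidates it is assigned one-to-one to the candidate with the
# largest overlap (ties broken by the smaller label), which resolves splits
# and merges deterministically.

voxel_keys <- function(obs) {
  paste(obs$coords[, 1], obs$coords[, 2], obs$coords[, 3])
}

overlap_voxels <- function(a, b) {
  length(intersect(voxel_keys(a), voxel_keys(b)))
}

# Greedy one-to-one maximum-overlap assignment between two observation lists.
# Returns a data.frame of (ia, ib, overlap) plus the unmatched indices.
greedy_overlap_assignment <- function(obs_a, obs_b) {
  pairs <- NULL
  if (length(obs_a) > 0L && length(obs_b) > 0L) {
    ov <- matrix(0L, length(obs_a), length(obs_b))
    keys_b <- lapply(obs_b, voxel_keys)
    for (ia in seq_along(obs_a)) {
      ka <- voxel_keys(obs_a[[ia]])
      for (ib in seq_along(obs_b))
        ov[ia, ib] <- sum(ka %in% keys_b[[ib]])
    }
    cand <- which(ov > 0, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      lab_a <- vapply(obs_a, function(o) o$label, 0L)[cand[, 1]]
      lab_b <- vapply(obs_b, function(o) o$label, 0L)[cand[, 2]]
      ord <- order(-ov[cand], lab_a, lab_b)
      cand <- cand[ord, , drop = FALSE]
      used_a <- logical(length(obs_a))
      used_b <- logical(length(obs_b))
      keep <- logical(nrow(cand))
      for (r in seq_len(nrow(cand))) {
        ia <- cand[r, 1]; ib <- cand[r, 2]
        if (!used_a[ia] && !used_b[ib]) {
          keep[r] <- TRUE
          used_a[ia] <- TRUE
          used_b[ib] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) > 0L)
        pairs <- data.frame(ia = cand[, 1], ib = cand[, 2],
                            overlap = ov[cand])
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(ia = integer(), ib = integer(), overlap = integer())
  list(pairs = pairs,
       unmatched_a = setdiff(seq_along(obs_a), pairs$ia),
       unmatched_b = setdiff(seq_along(obs_b), pairs$ib))
}

#' Match lesions between two time points
#'
#' Pairs observations from consecutive time points of the same patient and
#' agent by voxel overlap (any overlap qualifies; an optional minimum overlap
#' fraction of the smaller lesion can be required).
#'
#' @param obs_t,obs_tnext Lists of [lesion_observation()] from the two time
#'   points (same patient, same agent).
#' @param min_fraction Minimum `|A intersect B| / min(m_A, m_B)` to accept a
#'   match; default 0 implements the any-overlap rule.
#' @return List with `pairs` (data.frame `ia`, `ib`, `overlap` indexing the
#'   two input lists), `unmatched_t`, `unmatched_tnext` (index vectors).
#' @export
match_across_time <- function(obs_t, obs_tnext, min_fraction = 0) {
  all_obs <- c(obs_t, obs_tnext)
  if (length(all_obs) > 0L) {
    pid <- unique(vapply(all_obs, function(o) o$patient_id, ""))
    ag <- unique(vapply(all_obs, function(o) o$agent, ""))
    if (length(pid) > 1L) stop("observations from different patients")
    if (length(ag) > 1L) stop("observations from different agents")
  }
  res <- greedy_overlap_assignment(obs_t, obs_tnext)
  if (min_fraction > 0 && nrow(res$pairs) > 0L) {
    m_a <- vapply(res$pairs$ia, function(i) nrow(obs_t[[i]]$coords), 0L)
    m_b <- vapply(res$pairs$ib, function(i) nrow(obs_tnext[[i]]$coords), 0L)
    ok <- res$pairs$overlap / pmin(m_a, m_b) >= min_fraction
    dropped_a <- res$pairs$ia[!ok]
    dropped_b <- res$pairs$ib[!ok]
    res$pairs <- res$pairs[ok, , drop = FALSE]
    res$unmatched_a <- sort(c(res$unmatched_a, dropped_a))
    res$unmatched_b <- sort(c(res$unmatched_b, dropped_b))
  }
  list(pairs = res$pairs, unmatched_t = res$unmatched_a,
       unmatched_tnext = res$unmatched_b)
}

#' Build single-agent trajectories by chaining time-point matches
#'
#' Chains [match_across_time()] over consecutive time points: an observation
#' at t+1 joins the trajectory of the observation at t it overlaps most;
#' unmatched observations start new trajectories.
#'
#' @param observations List of [lesion_observation()] for one patient and one
#'   agent, any time points.
#' @param n_timepoints Number of time points N (time indices 0..N-1).
#' @param min_fraction Passed to [match_across_time()].
#' @return List of `lesion_trajectory` objects, each a list with
#'   `patient_id`, `trajectory_id` and `observations` (named
#'   `t<i>_<agent>`).
#' @export
build_trajectories <- function(observations, n_timepoints,
                               min_fraction = 0) {
  if (length(observations) == 0L) return(list())
  pid <- unique(vapply(observations, function(o) o$patient_id, ""))
  agent <- unique(vapply(observations, function(o) o$agent, ""))
  stopifnot(length(pid) == 1L, length(agent) == 1L)
  tidx <- vapply(observations, function(o) o$time_index, 0L)
  if (any(tidx >= n_timepoints))
    stop("time_index >= n_timepoints")
  by_t <- lapply(0:(n_timepoints - 1L),
                 function(t) observations[tidx == t])
  # traj_of[[t]][i]: trajectory id of observation i at time t
  trajs <- list()
  traj_of <- vector("list", n_timepoints)
  new_traj <- function(obs) {
    id <- length(trajs) + 1L
    trajs[[id]] <<- list(patient_id = pid,
                         trajectory_id = sprintf("%s_%s_%03d", pid, agent, id),
                         observations = stats::setNames(
                           list(obs), sprintf("t%d_%s", obs$time_index, agent)))
    id
  }
  traj_of[[1]] <- vapply(by_t[[1]], new_traj, 0L)
  if (n_timepoints > 1L) for (t in 2:n_timepoints) {
    prev <- by_t[[t - 1L]]
    curr <- by_t[[t]]
    m <- match_across_time(prev, curr, min_fraction)
    traj_of[[t]] <- integer(length(curr))
    if (nrow(m$pairs) > 0L) for (r in seq_len(nrow(m$pairs))) {
      id <- traj_of[[t - 1L]][m$pairs$ia[r]]
      obs <- curr[[m$pairs$ib[r]]]
      trajs[[id]]$observations[[sprintf("t%d_%s", obs$time_index, agent)]] <- obs
      traj_of[[t]][m$pairs$ib[r]] <- id
    }
    for (i in m$unmatched_tnext)
      traj_of[[t]][i] <- new_traj(curr[[i]])
  }
  lapply(trajs, function(tr) structure(tr, class = "lesion_trajectory"))
}

#' @export
print.lesion_trajectory <- function(x, ...) {
  cat(sprintf("lesion_trajectory %s [%s]: %s\n", x$trajectory_id,
              x$patient_id, paste(names(x$observations), collapse = ", ")))
  invisible(x)
}

traj_overlap <- function(ta, tb) {
  # total voxel overlap across shared time points
  tot <- 0L
  for (nm_a in names(ta$observations)) {
    t_a <- ta$observations[[nm_a]]$time_index
    for (nm_b in names(tb$observations)) {
      if (tb$observations[[nm_b]]$time_index == t_a)
        tot <- tot + overlap_voxels(ta$observations[[nm_a]],
                                    tb$observations[[nm_b]])
    }
  }
  tot
}

#' Merge Gd and USPIO trajectories of one patient
#'
#' A Gd trajectory and a USPIO trajectory are declared the same lesion when
#' their voxel sets overlap at any shared time point; assignment is
#' one-to-one by maximum total overlap. Trajectories enhanced by only one
#' agent are kept with the other agent absent (their feature blocks are
#' later zero-filled).
#'
#' @param gd_trajs,uspio_trajs Lists of trajectories from
#'   [build_trajectories()] for the two agents (same patient).
#' @return List of merged `lesion_trajectory` objects.
#' @export
pair_across_agents <- function(gd_trajs, uspio_trajs) {
  if (length(gd_trajs) == 0L) return(uspio_trajs)
  if (length(uspio_trajs) == 0L) return(gd_trajs)
  pid_g <- unique(vapply(gd_trajs, function(x) x$patient_id, ""))
  pid_u <- unique(vapply(uspio_trajs, function(x) x$patient_id, ""))
  if (!identical(pid_g, pid_u)) stop("trajectories from different patients")
  ov <- matrix(0L, length(gd_trajs), length(uspio_trajs))
  for (a in seq_along(gd_trajs))
    for (b in seq_along(uspio_trajs))
      ov[a, b] <- traj_overlap(gd_trajs[[a]], uspio_trajs[[b]])
  cand <- which(ov > 0, arr.ind = TRUE)
  used_u <- logical(length(uspio_trajs))
  merged <- gd_trajs
  if (nrow(cand) > 0L) {
    ord <- order(-ov[cand], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    used_g <- logical(length(gd_trajs))
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, 1]; b <- cand[r, 2]
      if (!used_g[a] && !used_u[b]) {
        used_g[a] <- TRUE; used_u[b] <- TRUE
        merged[[a]]$observations <-
          c(merged[[a]]$observations, uspio_trajs[[b]]$observations)
      }
    }
  }
  c(merged, uspio_trajs[!used_u])
}
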