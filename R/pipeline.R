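# End-to-end orchestration of the two-tier analysis: masks -> observations
# -> trajectories (time + agent matching) -> feature matrix -> cluster-number
# fusion -> clustering -> separation test -> patient profiles -> regression.

#' Pipeline configuration
#'
#' Collects every tunable of a run; validated up front and serialized (with
#' an md5 stamp) into each output bundle so runs are auditable.
#'
#' @param feature_mode `"tensor"` (eigenvalues + hollowness) or `"volume"`.
#' @param hollow_mode `"continuous"` or `"binary"` hollowness.
#' @param standardize Standardize feature columns before clustering.
#' @param algorithm `"spectral"` or `"kmeans"`.
#' @param k `"auto"` (decision fusion) or a fixed integer.
#' @param k_range Candidate cluster numbers for the validity indices.
#' @param agents `c("gd", "uspio")` or `"gd"` for the Gd-only variant.
#' @param n_perm Separation-test null draws.
#' @param gap_B Gap-statistic reference draws.
#' @param min_overlap_fraction Minimum overlap fraction for time matching
#'   (0 = any overlap, the default rule).
#' @param n_timepoints Number of baseline time points.
#' @param restarts K-means restarts.
#' @param seed Master RNG seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(feature_mode = c("tensor", "volume"),
                            hollow_mode = c("continuous", "binary"),
                            standardize = TRUE,
                            algorithm = c("spectral", "kmeans"),
                            k = "auto", k_range = 1:6,
                            agents = c("gd", "uspio"),
                            n_perm = 10000L, gap_B = 100L,
                            min_overlap_fraction = 0,
                            n_timepoints = 2L, restarts = 50L, seed = 1L) {
  cfg <- list(feature_mode = match.arg(feature_mode),
              hollow_mode = match.arg(hollow_mode),
              standardize = isTRUE(standardize),
              algorithm = match.arg(algorithm),
              k = if (identical(k, "auto")) "auto" else as.integer(k),
              k_range = as.integer(k_range),
              agents = match.arg(agents, c("gd", "uspio"),
                                 several.ok = TRUE),
              n_perm = as.integer(n_perm), gap_B = as.integer(gap_B),
              min_overlap_fraction = min_overlap_fraction,
              n_timepoints = as.integer(n_timepoints),
              restarts = as.integer(restarts), seed = as.integer(seed))
  if (!identical(cfg$k, "auto") && cfg$k < 1L) stop("k must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Build merged trajectories for every patient of a volume set
#'
#' Extracts observations from each labeled volume, chains time-point
#' matches per agent and merges agents by overlap.
#'
#' @param volumes List of [mask_volume()].
#' @param n_timepoints Number of time points.
#' @param min_fraction Minimum overlap fraction for matching.
#' @return List of `lesion_trajectory` across all patients.
#' @export
volumes_to_trajectories <- function(volumes, n_timepoints,
                                    min_fraction = 0) {
  pids <- vapply(volumes, function(v) v$patient_id, "")
  out <- list()
  for (pid in sort(unique(pids))) {
    vols <- volumes[pids == pid]
    per_agent <- lapply(c("gd", "uspio"), function(agent) {
      obs <- unlist(lapply(vols[vapply(vols, function(v) v$agent, "") ==
                                  agent],
                           extract_observations), recursive = FALSE)
      build_trajectories(obs, n_timepoints, min_fraction)
    })
    out <- c(out, pair_across_agents(per_agent[[1]], per_agent[[2]]))
  }
  out
}

#' Run the full two-tier pipeline
#'
#' @param volumes List of [mask_volume()] (e.g. a synthetic cohort's
#'   `$volumes`, or loaded from disk with [load_mask_volume()]).
#' @param outcomes Outcome data.frame (see [patient_cardinalities()]).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, the feature TSV, labels
#'   CSV, JSON reports and the patient table TSV are written there.
#' @param run_separation Compute the separation test (skippable because it
#'   dominates runtime at large `n_perm`).
#' @param verbose Log stage-level counts via `message()`.
#' @return A `pipeline_result` bundle: `features`, `validity`, `model`,
#'   `separation`, `profiles`, `fit`, `counts`, `config`, `config_md5`.
#' @export
run_pipeline <- function(volumes, outcomes, config = pipeline_config(),
                         out_dir = NULL, run_separation = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  trajs <- volumes_to_trajectories(volumes, config$n_timepoints,
                                   config$min_overlap_fraction)
  n_obs <- sum(vapply(trajs, function(tr) length(tr$observations), 0L))
  say("matched %d observations into %d trajectories", n_obs, length(trajs))
  fm <- build_feature_matrix(trajs, config$n_timepoints,
                             mode = config$feature_mode,
                             hollow_mode = config$hollow_mode,
                             agents = config$agents,
                             standardize = config$standardize)
  validity <- NULL
  if (identical(config$k, "auto")) {
    validity <- estimate_cluster_number(fm, config$k_range,
                                        seed = derive_seed(config$seed, 1L),
                                        B = config$gap_B)
    K <- validity$fused_k
    say("validity votes [%s] -> fused k = %d",
        paste(validity$votes, collapse = ","), K)
  } else K <- config$k
  model <- if (K == 1L)
    # degenerate single-pattern case: tier 2 collapses to a regression on
    # the total active-lesion count
    new_cluster_model(rep(1L, nrow(fm$X)), 1L,
                      matrix(colMeans(fm$X), 1L), config$algorithm,
                      config$seed, within_ss(fm$X, rep(1L, nrow(fm$X))),
                      fm$row_ids)
  else if (config$algorithm == "spectral")
    spectral_cluster(fm, K, derive_seed(config$seed, 2L),
                     restarts = config$restarts)
  else kmeans_cluster(fm, K, derive_seed(config$seed, 2L),
                      restarts = config$restarts)
  say("clustered %d trajectories into %d clusters (sizes %s)",
      length(model$labels), K, paste(tabulate(model$labels, K),
                                     collapse = "/"))
  separation <- NULL
  if (run_separation && model$K >= 2L)
    separation <- separation_test(fm, model$labels, config$n_perm,
                                  seed = derive_seed(config$seed, 3L))
  profiles <- patient_cardinalities(model$labels, fm$patient_ids, K,
                                    outcomes)
  fit <- fit_patient_model(profiles, K)
  say("fit %d active patients, %d excluded (group C); R2 = %.3f",
      fit$n_active, sum(profiles$group == "C"), fit$r2_full)
  bundle <- structure(
    list(features = fm, validity = validity, model = model,
         separation = separation, profiles = profiles, fit = fit,
         counts = list(observations = n_obs, trajectories = length(trajs),
                       patients_active = fit$n_active,
                       patients_excluded = sum(profiles$group == "C")),
         config = config, config_md5 = object_md5(unclass(config))),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result [%s/%s/%s]: %d trajectories, K = %d\n",
              x$config$feature_mode, x$config$algorithm,
              paste(x$config$agents, collapse = "+"),
              x$counts$trajectories, x$model$K))
  if (!is.null(x$validity)) print(x$validity)
  print(x$fit)
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config = unclass(bundle$config),
                config_md5 = bundle$config_md5, seed = bundle$config$seed)
  write_feature_tsv(bundle$features, file.path(out_dir, "features.tsv"))
  utils::write.csv(
    data.frame(trajectory_id = bundle$features$row_ids,
               cluster = bundle$model$labels),
    file.path(out_dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  report <- list(
    stamp = stamp,
    validity = if (!is.null(bundle$validity))
      list(votes = as.list(bundle$validity$votes),
           fused_k = bundle$validity$fused_k,
           k_range = bundle$validity$k_range),
    model = list(K = bundle$model$K, algorithm = bundle$model$algorithm,
                 inertia = bundle$model$inertia,
                 sizes = tabulate(bundle$model$labels, bundle$model$K)),
    separation = if (!is.null(bundle$separation))
      unclass(bundle$separation),
    fit = unclass(bundle$fit),
    counts = bundle$counts)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(bundle$profiles,
                     file.path(out_dir, "patient_table.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

#' Run the 8-cell experiment grid
#'
#' Crosses feature mode (tensor/volume) x algorithm (spectral/kmeans) x
#' agent set (Gd+USPIO / Gd-only) and reports, per cell, the chosen K and
#' the leave-one-patient-out R^2 summaries.
#'
#' @param volumes,outcomes,config As in [run_pipeline()] (the config's own
#'   feature/algorithm/agents fields are overridden cell by cell).
#' @return data.frame with one row per cell: `feature_mode`, `algorithm`,
#'   `agents`, `K`, `r2_full`, `loo_pooled_r2`, `loo_r2_mean`,
#'   `loo_r2_var`.
#' @export
experiment_grid <- function(volumes, outcomes, config = pipeline_config()) {
  rows <- list()
  for (fmode in c("tensor", "volume"))
    for (alg in c("spectral", "kmeans"))
      for (ag in list(c("gd", "uspio"), "gd")) {
        cfg <- config
        cfg$feature_mode <- fmode
        cfg$algorithm <- alg
        cfg$agents <- ag
        res <- run_pipeline(volumes, outcomes, cfg, run_separation = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_mode = fmode, algorithm = alg,
          agents = paste(ag, collapse = "+"),
          K = res$model$K, r2_full = res$fit$r2_full,
          loo_pooled_r2 = res$fit$r2_loo_patient$pooled,
          loo_r2_mean = res$fit$r2_loo_patient$mean,
          loo_r2_var = res$fit$r2_loo_patient$var)
      }
  do.call(rbind, rows)
}
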