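#' Run a staged experiment and write all artifacts to a directory
#'
#' Orchestrates the standard pipeline with one master seed: `build` the
#' network, `train` it on its stimulus set, record `ongoing` activity,
#' optionally `perturb` it with one of the three post-training scenarios,
#' and `analyze` the recordings (overlaps, state segmentation, dwell-time
#' statistics, weight classes). Each stage's outputs are written as plain
#' text (spike tables, weight snapshots, CSV/JSON reports) so any analysis
#' can be recomputed from the artifacts alone, and a manifest records the
#' configuration hash, seeds and file inventory.
#'
#' @param cfg A [network_config()].
#' @param stages Character vector, subset of
#'   `c("build", "train", "ongoing", "perturb", "analyze")`, executed in
#'   this order.
#' @param out_dir Output directory (created if needed).
#' @param train_ms,ongoing_ms,perturb_ms Stage durations, ms. Training
#'   defaults to the Q-scaled schedule length.
#' @param scenario Perturbation scenario (see [perturbation_schedule()]).
#' @param snapshot_every_ms Cadence of full weight snapshots during
#'   sessions.
#' @param plasticity Apply plasticity during the post-training stages?
#'   (Training always uses plasticity.)
#'
#' @return A `plastnet_manifest` list (also written as `manifest.json` or
#'   `manifest.yaml`): config hash, stage log, seeds, file inventory.
#' @export
run_experiment <- function(cfg, stages = c("build", "train", "analyze"),
                           out_dir, train_ms = NULL, ongoing_ms = 60000,
                           perturb_ms = 60000,
                           scenario = c("random", "mixed", "novel"),
                           snapshot_every_ms = 60000, plasticity = TRUE) {
  stopifnot(inherits(cfg, "plastnet_config"))
  scenario <- match.arg(scenario)
  allowed <- c("build", "train", "ongoing", "perturb", "analyze")
  if (!all(stages %in% allowed))
    stop("run_experiment: unknown stage(s): ",
         paste(setdiff(stages, allowed), collapse = ", "), call. = FALSE)
  stages <- allowed[allowed %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(cfg, cfg_path)
  files <- c(config = cfg_path)
  log <- list()
  net <- NULL; ses <- NULL

  tic <- function() proc.time()[["elapsed"]]
  t_start <- tic()

  if ("build" %in% stages) {
    net <- build_network(cfg)
    files["weights_initial"] <- file.path(out_dir, "weights_initial.tsv")
    write_weights(net, files[["weights_initial"]], time_ms = 0)
    files["clusters"] <- file.path(out_dir, "clusters.tsv")
    eta <- net$clusters$eta
    readr::write_tsv(tibble::tibble(
      stimulus = rep(seq_len(nrow(eta)), times = ncol(eta)),
      neuron = rep(seq_len(ncol(eta)), each = nrow(eta)),
      member = as.integer(eta)), files[["clusters"]])
    log$build <- list(edges = nrow(net$edges), elapsed_s = tic() - t_start)
  }
  if ("train" %in% stages) {
    if (is.null(net)) stop("run_experiment: 'train' needs 'build'",
                           call. = FALSE)
    sched <- training_schedule(
      net$clusters, session_ms = train_ms %||% (60000 * cfg$Q),
      amplitude = cfg$h_st, seed = substream_seed(cfg$seed, "schedule"))
    t0 <- tic()
    ses <- run_session(net, sched,
                       snapshot_times = seq(0, attr(sched, "session_ms"),
                                            by = snapshot_every_ms))
    net <- ses$network
    files["spikes_training"] <- file.path(out_dir, "spikes_training.tsv")
    write_spike_table(ses, files[["spikes_training"]])
    files["weights_post_training"] <-
      file.path(out_dir, "weights_post_training.tsv")
    write_weights(net, files[["weights_post_training"]], time_ms = ses$t_end)
    files["class_series_training"] <-
      file.path(out_dir, "class_series_training.csv")
    readr::write_csv(ses$class_series, files[["class_series_training"]])
    log$train <- list(presentations = nrow(sched), spikes = nrow(ses$spikes),
                      elapsed_s = tic() - t0)
  }
  if ("ongoing" %in% stages || "perturb" %in% stages) {
    if (is.null(ses)) stop("run_experiment: post-training stages need 'train'",
                           call. = FALSE)
    stage <- intersect(stages, c("ongoing", "perturb"))[1]
    t0 <- tic()
    sched <- if (stage == "ongoing") empty_schedule(ongoing_ms) else
      perturbation_schedule(scenario, N_E = cfg$N_E, f = cfg$f,
                            session_ms = perturb_ms,
                            set2 = assign_clusters(
                              cfg$N_E, cfg$Q, cfg$f,
                              seed = substream_seed(cfg$seed, "perturbation")),
                            amplitude = cfg$h_st,
                            seed = substream_seed(cfg$seed, "perturbation"))
    ses <- run_session(net, sched, resume = ses, plasticity = plasticity)
    net <- ses$network
    files[paste0("spikes_", stage)] <-
      file.path(out_dir, paste0("spikes_", stage, ".tsv"))
    write_spike_table(ses, files[[paste0("spikes_", stage)]])
    files["weights_final"] <- file.path(out_dir, "weights_final.tsv")
    write_weights(net, files[["weights_final"]], time_ms = ses$t_end)
    log[[stage]] <- list(spikes = nrow(ses$spikes), elapsed_s = tic() - t0)
  }
  if ("analyze" %in% stages) {
    if (is.null(ses)) stop("run_experiment: 'analyze' needs recordings",
                           call. = FALSE)
    ov <- overlap_series(ses$spikes, net$clusters, ses$t0, ses$t_end)
    states <- detect_states(ov)
    files["states"] <- file.path(out_dir, "state_segments.csv")
    readr::write_csv(states, files[["states"]])
    wcls <- mean_weights_by_class(net)
    report <- list(duration_stats = as.list(duration_stats(states)),
                   weight_classes = as.list(wcls),
                   class_series = ses$class_series)
    files["report"] <- file.path(out_dir, "analysis_report.json")
    write_report(report, files[["report"]])
    log$analyze <- list(segments = nrow(states))
  }

  manifest <- list(package_version = as.character(utils::packageVersion(
                     "plastnet")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   master_seed = cfg$seed,
                   substreams = as.list(.substreams),
                   stages = stages, log = log, files = as.list(files),
                   elapsed_s = tic() - t_start)
  man_path <- file.path(out_dir, "manifest.json")
  write_report(manifest, man_path)
  invisible(structure(manifest, class = "plastnet_manifest"))
}

write_report <- function(x, path) {
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  } else {
    yaml::write_yaml(x, sub("\\.json$", ".yaml", path))
  }
  invisible(path)
}
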