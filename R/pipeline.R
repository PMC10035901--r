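#' Pipeline configuration
#'
#' Reads (or builds with defaults) the YAML configuration shared by the
#' pipeline stages: arena geometry and calibration, interaction criteria,
#' community-detection settings and comparison settings. Every stage
#' writes the fully resolved configuration next to its outputs so a run
#' is self-describing.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A named list with elements `arena`, `criteria`, `community`
#'   (`weight`, `seed`, `resolution`) and `compare` (`alpha`, `local_stat`).
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(
    arena = list(radius_mm = 60, fps = 24, px_per_mm = NULL,
                 center_x = 0, center_y = 0),
    criteria = list(distance_threshold_bl = 2, body_length_mm = 2,
                    min_duration_s = 0.5, gap_tolerance_frames = 0),
    community = list(weight = "duration", seed = 0, resolution = 1.0),
    compare = list(alpha = 0.05, local_stat = "median"))
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (sec in intersect(names(user), names(cfg)))
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

config_arena <- function(cfg) {
  do.call(arena_spec, cfg$arena[!vapply(cfg$arena, is.null, TRUE)])
}

config_criteria <- function(cfg) do.call(interaction_criteria, cfg$criteria)

write_resolved_config <- function(cfg, dir) {
  yaml::write_yaml(cfg, file.path(dir, "config_resolved.yaml"))
}

#' Pipeline stage: simulate tracking files
#'
#' Writes `n_groups` simulated group recordings (CSV tracking files) for
#' a preset, with per-group seeds derived from `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param preset_name `"ctrl_like"` or `"coc_like"`.
#' @param n_groups Number of groups to simulate.
#' @param seed Base seed; group `g` uses `seed + g - 1`.
#' @param config Optional [sim_config()] overriding the preset.
#' @return Character vector of the written file paths, invisibly.
#' @export
run_simulate <- function(out_dir, preset_name = "ctrl_like", n_groups = 1,
                         seed = 1L, config = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_groups)
  for (g in seq_len(n_groups)) {
    cfg <- if (is.null(config)) preset(preset_name, seed = seed + g - 1L)
           else { config$seed <- as.integer(seed + g - 1L); config }
    traj <- simulate_arena(cfg)
    paths[g] <- file.path(out_dir, sprintf("%s_group%02d.csv", preset_name, g))
    write_trajectories(traj, paths[g])
  }
  invisible(paths)
}

#' Pipeline stage: detect interactions
#'
#' Reads each tracking file, applies the interaction criteria and writes
#' one events CSV per input (`<name>_events.csv`) into `out_dir`, along
#' with the resolved configuration.
#'
#' @param tracking_files Character vector of tracking CSV paths.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()] list.
#' @return Character vector of events CSV paths, invisibly.
#' @export
run_detect <- function(tracking_files, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arena <- config_arena(config)
  criteria <- config_criteria(config)
  out <- vapply(tracking_files, function(f) {
    traj <- read_tracking(f, arena)
    ev <- detect_events(traj, criteria)
    dest <- file.path(out_dir,
                      paste0(sub("\\.[^.]+$", "", basename(f)), "_events.csv"))
    write_events(ev, dest)
    # roster travels alongside so isolated flies survive the round trip
    writeLines(traj$roster, sub("_events\\.csv$", "_roster.txt", dest))
    dest
  }, character(1))
  write_resolved_config(config, out_dir)
  invisible(unname(out))
}

#' Pipeline stage: build networks and measures
#'
#' Builds the SIN for each events CSV (using the roster file written by
#' [run_detect()] when present) and writes, per network: a GraphML file,
#' the local measure table, the global summary row, the community
#' partition and the middle-level statistics.
#'
#' @param events_files Character vector of events CSV paths.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()] list.
#' @param condition Population label stored on the graphs.
#' @return List of `sin` objects, invisibly.
#' @export
run_network <- function(events_files, out_dir, config = pipeline_config(),
                        condition = "") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sins <- lapply(events_files, function(f) {
    ev <- read_events(f)
    stem <- sub("_events\\.csv$", "", basename(f))
    roster_file <- sub("_events\\.csv$", "_roster.txt", f)
    roster <- if (file.exists(roster_file)) readLines(roster_file) else NULL
    s <- build_sin(ev, roster = roster, label = stem, condition = condition)
    export_graph(s, file.path(out_dir, paste0(stem, ".graphml")), "graphml")
    lt <- local_measure_table(s)
    utils::write.csv(lt$per_node,
                     file.path(out_dir, paste0(stem, "_local.csv")),
                     row.names = FALSE)
    utils::write.csv(global_summary(s),
                     file.path(out_dir, paste0(stem, "_global.csv")),
                     row.names = FALSE)
    part <- louvain_partition(s, weight = config$community$weight,
                              seed = config$community$seed,
                              resolution = config$community$resolution)
    write_partition(part, file.path(out_dir, paste0(stem, "_communities.csv")))
    utils::write.csv(community_stats(s, part),
                     file.path(out_dir, paste0(stem, "_middle.csv")),
                     row.names = FALSE)
    s
  })
  write_resolved_config(config, out_dir)
  invisible(sins)
}

#' Pipeline stage: compare two populations
#'
#' Runs the Welch-corrected comparisons between two populations of
#' networks at all three levels and writes one comparison CSV per level
#' plus the pooled local-measure correlation matrix of each population.
#'
#' @param sins_a,sins_b Lists of `sin` objects (e.g. from [run_network()]).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()] list.
#' @return Named list of comparison tables, invisibly.
#' @export
run_compare <- function(sins_a, sins_b, out_dir, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  alpha <- config$compare$alpha
  res <- list(
    global = compare_measures(sins_a, sins_b, "global", alpha = alpha),
    local = compare_measures(sins_a, sins_b, "local-medians",
                             local_stat = config$compare$local_stat,
                             alpha = alpha),
    middle = compare_measures(sins_a, sins_b, "middle", alpha = alpha))
  for (lev in names(res))
    utils::write.csv(res[[lev]],
                     file.path(out_dir, paste0("compare_", lev, ".csv")),
                     row.names = FALSE)
  utils::write.csv(measure_correlations(sins_a),
                   file.path(out_dir, "correlations_a.csv"))
  utils::write.csv(measure_correlations(sins_b),
                   file.path(out_dir, "correlations_b.csv"))
  write_resolved_config(config, out_dir)
  invisible(res)
}
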