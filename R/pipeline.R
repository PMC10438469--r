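#' Default run configuration
#'
#' The pipeline configuration is a plain list (serialisable to YAML):
#' input paths (or `simulate: yes` plus simulator settings), typing
#' parameters, neighbor-graph parameters, follow-up horizons and seeds.
#' Every run writes the fully resolved configuration next to its outputs,
#' so an output directory is reproducible from its own contents.
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
run_config <- function(...) {
  cfg <- list(
    simulate = TRUE,
    sim_seed = 1L,
    tracks_dir = NULL,          # tabular forest directory when simulate = FALSE
    stain_file = NULL,
    axis_file = NULL,
    thresholds = NULL,          # NULL = per-marker Otsu
    max_match_distance = 10,
    pre_align = FALSE,
    k_candidates = 20L,
    cutoff = 2,
    horizons_h = c(2, 10),
    selection_delay_h = 1,
    separation_seed = 17L,
    compute_separation = FALSE, # per-frame graphs are the expensive stage
    axis_step = 0.25,
    max_frame_gap = 5L
  )
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Run the full analysis pipeline
#'
#' Chains the stages end to end: obtain inputs (simulate or read), call and
#' match end-point types, backpropagate, project onto the crypt-villus
#' axis, measure migration speeds, optionally measure neighbor and sister
#' separation, and compute the lineage statistics. All tables, a
#' machine-readable `summary.json` and the resolved `config.yaml` are
#' written to `out_dir`. Deterministic given the seeds in the
#' configuration.
#'
#' @param config list from [run_config()], or a path to a YAML file with
#'   the same fields.
#' @param out_dir output directory.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- utils::modifyList(run_config(), yaml::read_yaml(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(stage, ...) message("[", stage, "] ", ...)

  if (isTRUE(config$simulate)) {
    log_stage("simulate", "seed ", config$sim_seed)
    ds <- simulate_crypt(sim_config(), seed = config$sim_seed)
    forest <- ds$forest; stain <- ds$stain; axis_df <- ds$axis
  } else {
    log_stage("load", "reading inputs")
    if (is.null(config$tracks_dir) || !file.exists(config$tracks_dir)) {
      stop("load stage: tracks_dir missing or not found")
    }
    forest <- read_forest(config$tracks_dir, format = "tabular")
    if (is.null(config$stain_file) || !file.exists(config$stain_file)) {
      stop("typing stage: stain file missing or not found")
    }
    stain <- read_stain_table(config$stain_file)
    axis_df <- if (!is.null(config$axis_file)) read_axis_annotations(config$axis_file)
  }

  log_stage("type-endpoints", nrow(stain), " stained cells, gate ",
            config$max_match_distance, " um")
  thresholds <- config$thresholds
  if (!is.null(thresholds)) thresholds <- unlist(thresholds)
  typing <- assign_endpoint_types(forest, stain, thresholds = thresholds,
                                  max_match_distance = config$max_match_distance,
                                  pre_align = config$pre_align)
  log_stage("type-endpoints", "match rate ", round(100 * typing$match_rate, 1), "%")

  log_stage("backprop", "propagating types")
  typed <- backpropagate(forest, typing)
  write_typed_forest(typed, file.path(out_dir, "typed_forest"))
  utils::write.csv(typed$transitions, file.path(out_dir, "transitions.csv"),
                   row.names = FALSE)
  log_stage("backprop", nrow(typed$transitions), " transitions, ",
            if (is.null(typed$conflicts)) 0L else nrow(typed$conflicts), " conflicts")

  axis_pos <- NULL
  speeds <- NULL
  if (!is.null(axis_df)) {
    log_stage("axis", "projecting onto crypt-villus axis")
    axis_pos <- axis_positions(forest, axis_df, step = config$axis_step,
                               max_frame_gap = config$max_frame_gap)
    utils::write.csv(axis_pos, file.path(out_dir, "axis_positions.csv"),
                     row.names = FALSE)
    speeds <- migration_speeds(forest, axis_pos)
    speeds$type <- unname(typed$track_types[speeds$track_id])
    utils::write.csv(speeds, file.path(out_dir, "migration_speeds.csv"),
                     row.names = FALSE)
  }

  separation <- NULL
  if (isTRUE(config$compute_separation)) {
    log_stage("separation", "horizons ", paste(config$horizons_h, collapse = ", "), " h")
    separation <- sister_separation(typed, horizons_h = config$horizons_h,
                                    k_candidates = config$k_candidates,
                                    cutoff = config$cutoff,
                                    selection_delay_h = config$selection_delay_h,
                                    seed = config$separation_seed)
    utils::write.csv(separation, file.path(out_dir, "sister_separation.csv"),
                     row.names = FALSE)
  }

  log_stage("stats", "lineage statistics")
  hist <- sister_type_histogram(typed)
  ages <- endpoint_ages(typed)
  cycles <- cycle_durations(typed)
  census <- two_type_subtrees(typed)
  utils::write.csv(as.data.frame.table(hist$raw, responseName = "count"),
                   file.path(out_dir, "sister_histogram.csv"), row.names = FALSE)

  summary <- list(
    n_tracks = nrow(forest$tracks),
    n_endpoint = length(endpoint_tracks(forest)),
    match_rate = typing$match_rate,
    n_conflicts = length(typing$conflicts),
    n_transitions = nrow(typed$transitions),
    sister_same_type_fraction = hist$same_type_fraction,
    n_sister_pairs = hist$n_pairs,
    mean_cycle_h = lapply(cycles[vapply(cycles, length, 1L) > 0], mean),
    mean_age_h = lapply(ages[vapply(ages, length, 1L) > 0], mean),
    subtree_counts = as.list(census$counts),
    mean_speed_um_h = if (!is.null(speeds))
      lapply(split(speeds$speed_um_h, speeds$type), mean),
    separation = if (!is.null(separation)) separation
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(summary)
}
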