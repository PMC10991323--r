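#' Run the full trail-assay analysis
#'
#' End-to-end orchestration: for every ant in the experiment table, read its
#' frame sequence, bin it, segment and track the ant, compute the on-trail
#' metrics; then accumulate per-group heatmaps and run the statistical
#' battery (ln(y+1), one-way ANOVA, Dunnett versus the control, and —
#' optionally — pairwise t-tests between preparations at matched
#' concentrations). Analysis starts at the first valid detection and uses at
#' most the configured duration. Per-ant failures are recorded and skipped;
#' the run aborts only if an entire group ends up empty.
#'
#' @param cfg Run configuration, as returned by [read_run_config()] or an
#'   equivalent list with elements `arena`, `trail`, `spatial_factor`,
#'   `temporal_factor`, `seg`, `threshold_mm`, `heatmap_cell_mm`,
#'   `experiment` (tibble: `ant_id`, `source`, `preparation`,
#'   `concentration`), `control_label`, `out_dir`, `seed`.
#' @param write_outputs Write CSV outputs and a manifest under
#'   `cfg$out_dir`.
#' @return Object of class `trail_run`: list with `metrics` (per-ant tibble),
#'   `group_data`, `heatmaps` (named list of `trail_heatmap`), `anova`,
#'   `dunnett`, `failures`, `manifest`.
#' @export
run_experiment <- function(cfg, write_outputs = TRUE) {
  stopifnot(!is.null(cfg$experiment), nrow(cfg$experiment) > 0)
  assert_trail_in_arena(cfg$trail, cfg$arena)
  exp_tab <- tibble::as_tibble(cfg$experiment)
  conc <- as.character(exp_tab$concentration)
  no_conc <- is.na(conc) | conc %in% c("", "NA")   # "NA" survives CSV round trips
  exp_tab$group <- ifelse(no_conc, exp_tab$preparation,
                          paste(exp_tab$preparation, conc, sep = ":"))

  metrics <- list(); trajs <- list(); failures <- list()
  for (i in seq_len(nrow(exp_tab))) {
    ant <- exp_tab[i, ]
    res <- tryCatch(
      analyse_one_ant(ant$source, cfg),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <- tibble::tibble(
        ant_id = ant$ant_id, error = conditionMessage(res))
      next
    }
    metrics[[length(metrics) + 1]] <- dplyr::bind_cols(
      tibble::tibble(ant_id = ant$ant_id, group = ant$group), res$metrics)
    tr <- res$trajectory
    tr$ant_id <- ant$ant_id
    tr$group <- ant$group
    trajs[[length(trajs) + 1]] <- tr
  }
  metrics <- dplyr::bind_rows(metrics)
  trajs <- dplyr::bind_rows(trajs)
  failures <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(ant_id = character(), error = character())

  missing_groups <- setdiff(unique(exp_tab$group), unique(metrics$group))
  if (length(missing_groups) > 0) {
    abort(sprintf("whole group(s) produced no usable trajectory: %s",
                  toString(missing_groups)), class = "anttrail_run_error")
  }

  heatmaps <- purrr::map(
    split(trajs, trajs$group),
    ~ accumulate_heatmap(.x, cfg$arena, cfg$heatmap_cell_mm)
  )

  group_data <- dplyr::transmute(metrics, ant_id = .data$ant_id,
                                 group = .data$group, y_mm = .data$on_trail_mm)
  n_groups <- dplyr::n_distinct(group_data$group)
  anova_res <- if (n_groups >= 2 && all(table(group_data$group) >= 2)) {
    one_way_anova(group_data)
  }
  dunnett_res <- if (!is.null(anova_res) && cfg$control_label %in% group_data$group) {
    dunnett_vs_control(group_data, control = cfg$control_label)
  }

  manifest <- list(
    package_version = as.character(packageVersion("anttrail")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = cfg$seed,
    config = cfg[c("spatial_factor", "temporal_factor", "threshold_mm",
                   "heatmap_cell_mm", "control_label")],
    n_ants = nrow(exp_tab), n_failed = nrow(failures),
    detection_rate = if (nrow(trajs)) mean(trajs$valid) else NA_real_
  )

  run <- structure(
    list(metrics = metrics, group_data = group_data, heatmaps = heatmaps,
         anova = anova_res, dunnett = dunnett_res, failures = failures,
         manifest = manifest),
    class = "trail_run"
  )
  if (write_outputs) write_run_outputs(run, cfg)
  run
}

analyse_one_ant <- function(source, cfg) {
  video <- if (inherits(source, "ant_video")) source else
    read_frames(source, frame_rate_hz = cfg$arena$frame_rate_hz,
                px_per_mm = cfg$arena$px_per_mm)
  bv <- bin_video(video, cfg$spatial_factor, cfg$temporal_factor)
  det <- track_video(bv, cfg$seg, trail = cfg$trail)
  # analysis window: from first valid detection, at most the configured duration
  first <- which(det$valid)[1]
  if (is.na(first)) {
    abort("no valid detections in video", class = "anttrail_empty_trajectory")
  }
  max_frames <- floor(cfg$arena$duration_s * 1000 / bv$frame_period_ms)
  det <- det[first:min(nrow(det), first + max_frames - 1), ]
  det$frame <- seq_len(nrow(det))
  traj <- build_trajectory(det, cfg$seg, frame_period_ms = bv$frame_period_ms)
  traj <- on_trail_series(traj, cfg$trail, cfg$threshold_mm)
  list(trajectory = traj, metrics = trail_distance(traj))
}

write_run_outputs <- function(run, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$metrics, file.path(cfg$out_dir, "metrics.csv"), row.names = FALSE)
  write.csv(run$failures, file.path(cfg$out_dir, "failures.csv"), row.names = FALSE)
  for (g in names(run$heatmaps)) {
    write.csv(run$heatmaps[[g]]$counts,
              file.path(cfg$out_dir, sprintf("heatmap_%s.csv", gsub("[^A-Za-z0-9._-]", "_", g))),
              row.names = FALSE)
  }
  if (!is.null(run$anova)) {
    write.csv(tidy(run$anova), file.path(cfg$out_dir, "anova.csv"), row.names = FALSE)
  }
  if (!is.null(run$dunnett)) {
    write.csv(tidy(run$dunnett), file.path(cfg$out_dir, "dunnett.csv"), row.names = FALSE)
  }
  yaml::write_yaml(run$manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(NULL)
}

#' @export
print.trail_run <- function(x, ...) {
  cat(sprintf("<trail_run> %d ants analysed, %d failed, %d group(s)\n",
              nrow(x$metrics), nrow(x$failures),
              dplyr::n_distinct(x$metrics$group)))
  if (!is.null(x$anova)) print(x$anova)
  invisible(x)
}

#' Generate a seeded synthetic fixture set
#'
#' Writes rendered videos (PNG sequences) and matching ground-truth
#' trajectory CSVs for a table of ants, ready to be analysed with
#' [run_experiment()]; used by the test-suite and the demo. Each ant's
#' behavioural bias toward the trail is taken from its `trail_attraction`
#' column, so group-level differences in walking distance arise from the
#' walk model itself.
#'
#' @param design Tibble with columns `ant_id`, `preparation`,
#'   `concentration`, `trail_attraction`, and optionally `seed` (defaults to
#'   the row number offset by `seed`).
#' @param arena An [arena_config()] (use a short `duration_s` for fixtures).
#' @param trail A [trail_line()].
#' @param rp A [render_params()].
#' @param walk Base [walk_params()]; per-ant attraction/seed override it.
#' @param out_dir Output directory; must not exist unless
#'   `overwrite = TRUE`.
#' @param seed Base seed for per-ant seeds.
#' @param overwrite Allow writing into an existing directory.
#' @return The experiment table (tibble with `ant_id`, `source`,
#'   `preparation`, `concentration`, `truth_csv`), invisibly writable as
#'   part of a run config.
#' @export
make_fixtures <- function(design, arena, trail, rp = render_params(),
                          walk = walk_params(), out_dir, seed = 1L,
                          overwrite = FALSE) {
  stopifnot(all(c("ant_id", "preparation", "concentration",
                  "trail_attraction") %in% names(design)))
  if (dir.exists(out_dir) && !overwrite) {
    abort(sprintf("output directory exists: %s (use overwrite = TRUE)", out_dir),
          class = "anttrail_output_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    ant <- design[i, ]
    wp <- walk_params(
      mean_speed_mm_s = walk$mean_speed_mm_s,
      turn_concentration = walk$turn_concentration,
      trail_attraction = ant$trail_attraction,
      pause_prob = walk$pause_prob,
      seed = if ("seed" %in% names(design)) ant$seed else seed + i
    )
    traj <- simulate_trajectory(wp, arena, trail)
    video <- render_frames(traj, arena, rp, trail)
    vid_dir <- file.path(out_dir, paste0("video_", ant$ant_id))
    write_frames(video, vid_dir)
    truth_csv <- file.path(out_dir, paste0("truth_", ant$ant_id, ".csv"))
    write.csv(
      traj[, c("frame", "t_s", "x_mm", "y_mm", "on_trail_true")],
      truth_csv, row.names = FALSE
    )
    rows[[i]] <- tibble::tibble(
      ant_id = ant$ant_id, source = vid_dir,
      preparation = ant$preparation, concentration = ant$concentration,
      truth_csv = truth_csv
    )
  }
  out <- dplyr::bind_rows(rows)
  write.csv(out, file.path(out_dir, "experiment.csv"), row.names = FALSE)
  out
}
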