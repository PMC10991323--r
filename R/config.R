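#' Arena configuration
#'
#' Describes the rectangular assay arena and the recording geometry. The
#' rendered video frame covers exactly the arena rectangle, so the frame size
#' in pixels is `round(height_mm * px_per_mm)` by `round(width_mm * px_per_mm)`.
#' Millimetre coordinates have their origin at the arena's top-left corner,
#' x increasing rightward and y downward (matching image row/column order).
#'
#' Defaults correspond to a 160 x 100 mm paper sheet recorded at 25 frames/s
#' for 3 minutes.
#'
#' @param width_mm,height_mm Arena size in millimetres.
#' @param px_per_mm Calibration: full-resolution pixels per millimetre.
#' @param frame_rate_hz Acquisition frame rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @return An object of class `arena_config`.
#' @examples
#' arena_config()
#' arena_config(width_mm = 160, height_mm = 90, px_per_mm = 2)
#' @export
arena_config <- function(width_mm = 160, height_mm = 100, px_per_mm = 4,
                         frame_rate_hz = 25, duration_s = 180) {
  stopifnot(
    is.numeric(width_mm), width_mm > 0,
    is.numeric(height_mm), height_mm > 0,
    is.numeric(px_per_mm), px_per_mm > 0,
    is.numeric(frame_rate_hz), frame_rate_hz > 0,
    is.numeric(duration_s), duration_s > 0
  )
  structure(
    list(
      width_mm = width_mm, height_mm = height_mm, px_per_mm = px_per_mm,
      frame_rate_hz = frame_rate_hz, duration_s = duration_s
    ),
    class = "arena_config"
  )
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf(
    "<arena_config> %g x %g mm, %g px/mm (%d x %d px), %g Hz, %g s\n",
    x$width_mm, x$height_mm, x$px_per_mm,
    round(x$height_mm * x$px_per_mm), round(x$width_mm * x$px_per_mm),
    x$frame_rate_hz, x$duration_s
  ))
  invisible(x)
}

#' Trail line geometry
#'
#' The line segment drawn on the arena paper onto which the test solution is
#' applied. All trail-following distances are measured against this segment.
#'
#' @param p1,p2 Numeric length-2 endpoints `(x, y)` in arena millimetres.
#' @return An object of class `trail_line`.
#' @examples
#' trail_line(c(10, 50), c(150, 50))
#' @export
trail_line <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (length(p1) != 2 || length(p2) != 2 || !all(is.finite(c(p1, p2)))) {
    abort("trail_line endpoints must be finite (x, y) pairs", class = "anttrail_geometry_error")
  }
  if (all(p1 == p2)) {
    abort("trail_line is degenerate: endpoints coincide", class = "anttrail_geometry_error")
  }
  structure(list(p1 = p1, p2 = p2), class = "trail_line")
}

#' @export
print.trail_line <- function(x, ...) {
  cat(sprintf("<trail_line> (%g, %g) -- (%g, %g) mm\n",
              x$p1[1], x$p1[2], x$p2[1], x$p2[2]))
  invisible(x)
}

# trail endpoints strictly inside (or on the boundary of) the arena
assert_trail_in_arena <- function(trail, arena) {
  pts <- rbind(trail$p1, trail$p2)
  ok <- all(pts[, 1] >= 0 & pts[, 1] <= arena$width_mm &
              pts[, 2] >= 0 & pts[, 2] <= arena$height_mm)
  if (!ok) {
    abort("trail line lies outside the arena", class = "anttrail_geometry_error")
  }
  invisible(TRUE)
}

#' Locomotion parameters for the synthetic ant walk
#'
#' Parameters of the correlated random walk used to generate ground-truth
#' trajectories. These are modelling assumptions of the test harness, not
#' measured locomotion statistics of any ant species.
#'
#' @param mean_speed_mm_s Walking speed while moving, mm/s.
#' @param turn_concentration Directional persistence: the per-step turning
#'   noise is normal with SD `1/sqrt(turn_concentration)` radians; `0` gives a
#'   fully uncorrelated walk (uniform random heading each step).
#' @param trail_attraction In `[0, 1]`: fraction of the angular gap between
#'   the current heading and the bearing to the nearest trail point that is
#'   closed at each step. `0` disables trail following.
#' @param pause_prob Per-step probability of not moving.
#' @param seed Integer seed; identical seeds yield identical trajectories.
#' @return An object of class `walk_params`.
#' @export
walk_params <- function(mean_speed_mm_s = 20, turn_concentration = 25,
                        trail_attraction = 0, pause_prob = 0.05, seed = 1L) {
  stopifnot(
    mean_speed_mm_s >= 0,
    turn_concentration >= 0,
    trail_attraction >= 0, trail_attraction <= 1,
    pause_prob >= 0, pause_prob <= 1
  )
  structure(
    list(
      mean_speed_mm_s = mean_speed_mm_s,
      turn_concentration = turn_concentration,
      trail_attraction = trail_attraction,
      pause_prob = pause_prob,
      seed = as.integer(seed)
    ),
    class = "walk_params"
  )
}

#' Rendering parameters for synthetic video frames
#'
#' The ant is drawn as a dark anti-aliased ellipse on a light background
#' crossed by a grey trail line (the printed "toner" line of the assay).
#' Intensities are on the `[0, 1]` grayscale; the ant must remain the darkest
#' extended object in every frame for background-subtraction tracking to
#' apply.
#'
#' @param ant_length_mm Ant body length (major axis of the ellipse).
#' @param ant_aspect Minor/major axis ratio of the body ellipse.
#' @param ant_intensity,background_intensity,line_intensity Grey levels.
#' @param line_halfwidth_mm Half-width of the drawn trail line.
#' @param noise_sd SD of additive Gaussian pixel noise (0 = noise-free).
#' @return An object of class `render_params`.
#' @export
render_params <- function(ant_length_mm = 5, ant_aspect = 0.4,
                          ant_intensity = 0.15, background_intensity = 0.85,
                          line_intensity = 0.55, line_halfwidth_mm = 1,
                          noise_sd = 0) {
  stopifnot(
    ant_length_mm > 0, ant_aspect > 0, ant_aspect <= 1,
    ant_intensity >= 0, ant_intensity < background_intensity,
    background_intensity <= 1, line_intensity >= 0, line_intensity <= 1,
    line_halfwidth_mm >= 0, noise_sd >= 0
  )
  if (ant_intensity >= line_intensity) {
    abort("ant_intensity must be below line_intensity so the ant stays the darkest object",
          class = "anttrail_config_error")
  }
  structure(
    list(
      ant_length_mm = ant_length_mm, ant_aspect = ant_aspect,
      ant_intensity = ant_intensity,
      background_intensity = background_intensity,
      line_intensity = line_intensity,
      line_halfwidth_mm = line_halfwidth_mm, noise_sd = noise_sd
    ),
    class = "render_params"
  )
}

#' Segmentation and trajectory-assembly parameters
#'
#' @param threshold_offset Intensity units below background at which a pixel
#'   counts as foreground in the difference image (grayscale `[0, 1]`).
#' @param min_area_px,max_area_px Accepted connected-component area range, in
#'   binned pixels.
#' @param max_gap_frames Longest run of missing detections that is bridged by
#'   linear interpolation when assembling a trajectory.
#' @param line_mask_halfwidth_mm Optional safety net: pixels within this
#'   distance of the trail line are excluded from candidate foreground (the
#'   static line normally vanishes in background subtraction anyway). `0`
#'   disables the mask.
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(threshold_offset = 0.15, min_area_px = 1,
                       max_area_px = 500, max_gap_frames = 3,
                       line_mask_halfwidth_mm = 0) {
  stopifnot(
    threshold_offset > 0,
    min_area_px >= 1, max_area_px >= min_area_px,
    max_gap_frames >= 0, line_mask_halfwidth_mm >= 0
  )
  structure(
    list(
      threshold_offset = threshold_offset,
      min_area_px = as.integer(min_area_px),
      max_area_px = as.integer(max_area_px),
      max_gap_frames = as.integer(max_gap_frames),
      line_mask_halfwidth_mm = line_mask_halfwidth_mm
    ),
    class = "seg_params"
  )
}

#' Read a pipeline run configuration from YAML
#'
#' The configuration bundles arena geometry, trail endpoints, binning factors,
#' segmentation parameters, the on-trail threshold, heatmap cell size, the
#' experiment table (ant id, video source, preparation, concentration), the
#' control label, output directory and seed. See the package vignette for the
#' schema and `run_experiment()` for its use.
#'
#' @param path Path to a YAML file.
#' @return A named list with parsed and validated components.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("config file not found: %s", path), class = "anttrail_input_error")
  }
  raw <- yaml::read_yaml(path)
  cfg <- list(
    arena = do.call(arena_config, raw$arena %||% list()),
    trail = trail_line(raw$trail$p1, raw$trail$p2),
    spatial_factor = raw$binning$spatial %||% 4L,
    temporal_factor = raw$binning$temporal %||% 4L,
    seg = do.call(seg_params, raw$segmentation %||% list()),
    threshold_mm = raw$threshold_mm %||% 5,
    heatmap_cell_mm = raw$heatmap_cell_mm %||% 2,
    control_label = raw$control_label %||% "control",
    out_dir = raw$out_dir %||% "anttrail-run",
    seed = as.integer(raw$seed %||% 1L),
    experiment = if (!is.null(raw$experiment)) {
      tibble::as_tibble(do.call(rbind, lapply(raw$experiment, as.data.frame)))
    } else {
      NULL
    }
  )
  assert_trail_in_arena(cfg$trail, cfg$arena)
  cfg
}
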