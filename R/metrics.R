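#' Classify trajectory samples as on-trail
#'
#' A sample counts as trail-following when it is valid and the distance from
#' the body centre to the trail segment is strictly below `threshold_mm`
#' (5 mm by default; a sample at exactly the threshold is off-trail).
#'
#' @param traj Trajectory tibble with `x_mm`, `y_mm`, `valid`.
#' @param trail A [trail_line()].
#' @param threshold_mm On-trail distance threshold, millimetres.
#' @return The trajectory with added columns `dist_mm` and `on_trail`
#'   (logical, `FALSE` for invalid samples), and a `threshold_mm` attribute.
#' @export
on_trail_series <- function(traj, trail, threshold_mm = 5) {
  if (nrow(traj) == 0) {
    abort("trajectory is empty", class = "anttrail_input_error")
  }
  d <- point_segment_distance(traj$x_mm, traj$y_mm, trail)
  out <- dplyr::mutate(
    traj,
    dist_mm = d,
    on_trail = .data$valid & !is.na(d) & d < threshold_mm
  )
  attr(out, "threshold_mm") <- threshold_mm
  out
}

#' Per-ant trail-following metrics
#'
#' Sums Euclidean step lengths between consecutive valid samples to obtain
#' the total path length, and accumulates the on-trail walked distance y —
#' the assay's response variable — over the steps whose *both* endpoints are
#' flagged on-trail. Steps spanning invalid samples, or non-adjacent frames,
#' contribute nothing. Set `rule = "either"` to instead credit steps with at
#' least one on-trail endpoint.
#'
#' @param traj Trajectory with an `on_trail` column (see [on_trail_series()]),
#'   or without one if `trail` is supplied.
#' @param trail Optional [trail_line()] used to compute the flags when absent.
#' @param threshold_mm Threshold passed to [on_trail_series()] if needed.
#' @param rule Step-attribution rule: `"both"` (default, conservative) or
#'   `"either"`.
#' @return One-row tibble: `total_path_mm`, `on_trail_mm`,
#'   `on_trail_fraction` (on-trail share of valid samples), `n_valid`,
#'   `duration_s`.
#' @export
trail_distance <- function(traj, trail = NULL, threshold_mm = 5,
                           rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (!"on_trail" %in% names(traj)) {
    if (is.null(trail)) {
      abort("supply a trail line or a trajectory with an on_trail column",
            class = "anttrail_input_error")
    }
    traj <- on_trail_series(traj, trail, threshold_mm)
  }
  n <- nrow(traj)
  if (n == 0) abort("trajectory is empty", class = "anttrail_input_error")
  if (length(traj$on_trail) != length(traj$valid)) {
    abort("on-trail flags misaligned with trajectory", class = "anttrail_input_error")
  }
  period_s <- attr(traj, "frame_period_ms") %||% NA_real_
  if (n >= 2) {
    i <- seq_len(n - 1)
    adjacent <- diff(traj$frame) == 1
    both_valid <- traj$valid[i] & traj$valid[i + 1] & adjacent
    L <- sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2)
    L[!both_valid | is.na(L)] <- 0
    on_step <- if (rule == "both") {
      traj$on_trail[i] & traj$on_trail[i + 1]
    } else {
      traj$on_trail[i] | traj$on_trail[i + 1]
    }
    total <- sum(L)
    on_mm <- sum(L[both_valid & on_step])
  } else {
    total <- 0; on_mm <- 0
  }
  tibble::tibble(
    total_path_mm = total,
    on_trail_mm = on_mm,
    on_trail_fraction = sum(traj$on_trail) / max(sum(traj$valid), 1),
    n_valid = sum(traj$valid),
    duration_s = if (is.na(period_s)) NA_real_ else n * period_s / 1000
  )
}

#' Accumulate a group occupancy heatmap
#'
#' Counts valid trajectory samples into a square grid over the arena,
#' accumulated over all ants of a group ("accumulated trajectories"). Cell
#' counts divided by their total give the spatial passage probability used
#' for display. Samples exactly on an interior cell edge go to the
#' higher-index cell; samples on the far arena boundary are clamped into the
#' last cell.
#'
#' @param traj_df Trajectory samples of one or more ants: tibble with
#'   `x_mm`, `y_mm`, `valid`, and optionally `ant_id` (used only to count
#'   ants).
#' @param arena An [arena_config()].
#' @param cell_mm Cell size in millimetres.
#' @return An object of class `trail_heatmap`: list with `counts`
#'   (rows = y cells, cols = x cells), `cell_mm`, `n_ants`, `arena`.
#' @export
accumulate_heatmap <- function(traj_df, arena, cell_mm = 2) {
  if (cell_mm <= 0) {
    abort("cell_mm must be positive", class = "anttrail_parameter_error")
  }
  nx <- ceiling(arena$width_mm / cell_mm)
  ny <- ceiling(arena$height_mm / cell_mm)
  keep <- traj_df$valid & is.finite(traj_df$x_mm) & is.finite(traj_df$y_mm)
  x <- traj_df$x_mm[keep]; y <- traj_df$y_mm[keep]
  ix <- pmin(floor(x / cell_mm) + 1, nx)
  iy <- pmin(floor(y / cell_mm) + 1, ny)
  counts <- matrix(tabulate((ix - 1) * ny + iy, nbins = nx * ny), ny, nx)
  structure(
    list(
      counts = counts, cell_mm = cell_mm,
      n_ants = if ("ant_id" %in% names(traj_df))
        dplyr::n_distinct(traj_df$ant_id) else 1L,
      arena = arena
    ),
    class = "trail_heatmap"
  )
}

#' @export
print.trail_heatmap <- function(x, ...) {
  cat(sprintf("<trail_heatmap> %d x %d cells of %g mm, %d ant(s), %d samples\n",
              nrow(x$counts), ncol(x$counts), x$cell_mm, x$n_ants, sum(x$counts)))
  invisible(x)
}

#' @export
as_tibble.trail_heatmap <- function(x, ...) {
  ny <- nrow(x$counts); nx <- ncol(x$counts)
  tot <- sum(x$counts)
  tibble::tibble(
    x_mm = rep((seq_len(nx) - 0.5) * x$cell_mm, each = ny),
    y_mm = rep((seq_len(ny) - 0.5) * x$cell_mm, nx),
    count = as.vector(x$counts),
    probability = if (tot > 0) as.vector(x$counts) / tot else 0
  )
}
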