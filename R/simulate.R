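#' Simulate a ground-truthed ant trajectory
#'
#' Generates a correlated random walk inside the arena with an optional
#' heading bias toward the trail line, sampled at the arena frame rate. The
#' walk reflects specularly at the walls and starts at the midpoint of the
#' left (short) wall heading inward, where the entry tube meets the arena in
#' the assay. Ground-truth trail distance and on-trail labels are retained
#' alongside the positions so every downstream stage can be validated.
#'
#' At each step the heading first receives wrapped-normal turning noise with
#' SD `1/sqrt(turn_concentration)` rad, then turns by a fraction
#' `trail_attraction` of the angular gap toward a pursuit target on the
#' trail: the nearest trail point advanced 5 mm along the line in the
#' direction of travel. Steering at a point ahead makes an attracted ant run
#' along the line — as trail-following ants do — rather than oscillate
#' across it.
#'
#' @param walk A [walk_params()].
#' @param arena An [arena_config()].
#' @param trail A [trail_line()]; must lie within the arena.
#' @param threshold_mm On-trail rule used for the ground-truth labels
#'   (strictly-less-than), in millimetres.
#' @return A tibble of class `ant_trajectory` with one row per frame:
#'   `frame`, `t_s`, `x_mm`, `y_mm`, `heading`, `dist_mm`, `on_trail_true`,
#'   `valid` (all `TRUE` for simulated truth), and a `frame_period_ms`
#'   attribute.
#' @examples
#' tr <- simulate_trajectory(walk_params(seed = 7), arena_config(duration_s = 10),
#'                           trail_line(c(10, 50), c(150, 50)))
#' head(tr)
#' @export
simulate_trajectory <- function(walk, arena, trail, threshold_mm = 5) {
  stopifnot(inherits(walk, "walk_params"), inherits(arena, "arena_config"))
  assert_trail_in_arena(trail, arena)

  n <- round(arena$duration_s * arena$frame_rate_hz)
  dt <- 1 / arena$frame_rate_hz
  w <- arena$width_mm; h <- arena$height_mm
  sigma_turn <- if (walk$turn_concentration > 0) 1 / sqrt(walk$turn_concentration) else Inf

  x <- numeric(n); y <- numeric(n); theta <- numeric(n)
  x[1] <- 1e-6; y[1] <- h / 2; theta[1] <- 0  # left short-wall midpoint, heading inward
  lookahead_mm <- 5                           # pursuit distance along the line

  # draw all randomness up front for speed and strict seed reproducibility
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(walk$seed)
  turn_noise <- if (is.finite(sigma_turn)) rnorm(n, 0, sigma_turn) else runif(n, -pi, pi)
  paused <- runif(n) < walk$pause_prob
  step_len <- walk$mean_speed_mm_s * dt

  for (i in seq_len(n - 1)) {
    th <- if (is.finite(sigma_turn)) theta[i] + turn_noise[i] else turn_noise[i]
    if (walk$trail_attraction > 0) {
      tgt <- trail_pursuit_target(x[i], y[i], th, trail, lookahead_mm)
      bearing <- atan2(tgt[2] - y[i], tgt[1] - x[i])
      th <- th + walk$trail_attraction * wrap_angle(bearing - th)
    }
    if (paused[i] || step_len == 0) {
      x[i + 1] <- x[i]; y[i + 1] <- y[i]; theta[i + 1] <- th
      next
    }
    nx <- x[i] + step_len * cos(th)
    ny <- y[i] + step_len * sin(th)
    # specular reflection at the walls (repeat in case a step crosses a corner)
    while (nx < 0 || nx > w || ny < 0 || ny > h) {
      if (nx < 0) { nx <- -nx; th <- pi - th }
      if (nx > w) { nx <- 2 * w - nx; th <- pi - th }
      if (ny < 0) { ny <- -ny; th <- -th }
      if (ny > h) { ny <- 2 * h - ny; th <- -th }
    }
    x[i + 1] <- nx; y[i + 1] <- ny; theta[i + 1] <- wrap_angle(th)
  }

  dist_mm <- point_segment_distance(x, y, trail)
  out <- tibble::tibble(
    frame = seq_len(n),
    t_s = (seq_len(n) - 1) * dt,
    x_mm = x, y_mm = y,
    heading = theta,
    dist_mm = dist_mm,
    on_trail_true = dist_mm < threshold_mm,
    valid = TRUE
  )
  attr(out, "frame_period_ms") <- 1000 * dt
  class(out) <- c("ant_trajectory", class(out))
  out
}

wrap_angle <- function(a) atan2(sin(a), cos(a))

# pursuit target for trail following: the nearest trail point advanced along
# the line (in whichever direction is closer to the current heading) by the
# lookahead distance, clamped to the segment. Steering at a point ahead makes
# an ant on the line travel along it instead of oscillating across it.
trail_pursuit_target <- function(x, y, heading, trail, lookahead) {
  v <- trail$p2 - trail$p1
  len <- sqrt(sum(v^2))
  tv <- v / len
  t0 <- ((x - trail$p1[1]) * tv[1] + (y - trail$p1[2]) * tv[2])
  t0 <- min(max(t0, 0), len)
  s <- if (cos(heading) * tv[1] + sin(heading) * tv[2] >= 0) 1 else -1
  t1 <- min(max(t0 + s * lookahead, 0), len)
  trail$p1 + t1 * tv
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Experimental group design for the walking-distance simulator
#'
#' Encodes the group structure of a trail assay: a set of
#' preparation/concentration groups, the sample size per group, and the
#' expected shift of each group's mean on the ln(y+1) scale relative to the
#' control. The control group must appear exactly once.
#'
#' @param groups Character vector of group labels (including the control), or
#'   a data frame with columns `preparation` and `concentration` whose pasted
#'   labels are used.
#' @param n_per_group Ants per group.
#' @param effect_profile Named numeric vector of ln-scale mean shifts versus
#'   control; groups not named get shift 0.
#' @param control Label of the control group.
#' @param control_mean_ln Control-group mean of ln(y+1) (ln-millimetres).
#' @param dispersion ln-scale within-group SD (common to all groups).
#' @param nonresponder_prob Probability that an ant never leaves the entry
#'   tube and is excluded before analysis.
#' @param seed Integer seed.
#' @return An object of class `group_design`.
#' @export
group_design <- function(groups, n_per_group = 15, effect_profile = NULL,
                         control = "control", control_mean_ln = 3,
                         dispersion = 0.6, nonresponder_prob = 0, seed = 1L) {
  if (is.data.frame(groups)) {
    groups <- paste(groups$preparation, groups$concentration, sep = ":")
  }
  groups <- as.character(groups)
  if (dispersion < 0) {
    abort("dispersion must be non-negative", class = "anttrail_parameter_error")
  }
  if (sum(groups == control) != 1) {
    abort("control group must be present exactly once", class = "anttrail_parameter_error")
  }
  if (n_per_group < 2) {
    abort("n_per_group must be at least 2", class = "anttrail_parameter_error")
  }
  shifts <- setNames(rep(0, length(groups)), groups)
  if (!is.null(effect_profile)) {
    unknown <- setdiff(names(effect_profile), groups)
    if (length(unknown)) {
      abort(sprintf("effect_profile names not in groups: %s", toString(unknown)),
            class = "anttrail_parameter_error")
    }
    shifts[names(effect_profile)] <- effect_profile
  }
  shifts[control] <- 0
  structure(
    list(
      groups = groups, n_per_group = as.integer(n_per_group),
      effect_profile = shifts, control = control,
      control_mean_ln = control_mean_ln, dispersion = dispersion,
      nonresponder_prob = nonresponder_prob, seed = as.integer(seed)
    ),
    class = "group_design"
  )
}

#' Group labels of a dose-ladder trail assay
#'
#' Builds the label set of a trail-following experiment: one group per
#' compound x concentration, plus any extra preparations (e.g. a gland
#' extract) and controls. With two compounds, five concentrations, one
#' extract and two controls this yields the 13-group layout of a
#' dose-response assay; two compounds at five concentrations with the same
#' controls and reference groups can be extended to larger designs.
#'
#' @param compounds Character vector of compound names.
#' @param concentrations Character (or numeric) concentration labels,
#'   e.g. `c("1e-3", "1e-2", "0.1", "1", "10")` ng/uL.
#' @param extras Extra single preparations tested as-is.
#' @param controls Control labels (the first is the conventional no-odorant
#'   control).
#' @return Character vector of group labels.
#' @examples
#' length(assay_groups())  # 13
#' @export
assay_groups <- function(compounds = c("2-dodecanol", "2-tridecanol"),
                         concentrations = c("1e-3", "1e-2", "0.1", "1", "10"),
                         extras = "tibia-extract",
                         controls = c("control", "hexane")) {
  c(controls, extras,
    as.vector(outer(compounds, concentrations, paste, sep = ":")))
}

#' Simulate per-ant walking distances for a group design
#'
#' Draws each ant's on-trail walked distance y (mm) so that `ln(y + 1)` is
#' normal with the design's group mean and common dispersion. This makes the
#' parametric assumptions of the downstream statistics true by construction.
#' Non-responders (ants that never leave the entry tube) are removed before
#' the table is returned; their count is kept as an attribute.
#'
#' @param design A [group_design()].
#' @return A tibble of class `group_data` with columns `ant_id`, `group`,
#'   `y_mm`, attributes `control` and `n_nonresponders`.
#' @examples
#' d <- group_design(assay_groups(), n_per_group = 15, seed = 42)
#' nrow(simulate_group_distances(d))  # 195
#' @export
simulate_group_distances <- function(design) {
  stopifnot(inherits(design, "group_design"))
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(design$seed)

  k <- length(design$groups)
  n <- design$n_per_group
  mu <- design$control_mean_ln + design$effect_profile
  Y <- rnorm(k * n, mean = rep(mu, each = n), sd = design$dispersion)
  out <- tibble::tibble(
    ant_id = paste0(rep(design$groups, each = n), "_", rep(seq_len(n), k)),
    group = rep(design$groups, each = n),
    y_mm = pmax(expm1(Y), 0)   # guard: y is a distance and cannot be negative
  )
  keep <- runif(nrow(out)) >= design$nonresponder_prob
  dropped <- sum(!keep)
  out <- out[keep, ]
  attr(out, "control") <- design$control
  attr(out, "n_nonresponders") <- dropped
  class(out) <- c("group_data", class(out))
  out
}
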