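#' Plot an occupancy heatmap
#'
#' Renders the accumulated occupancy grid as spatial passage probability,
#' dark background with yellow intensity for frequently visited cells, as
#' such assays are conventionally displayed.
#'
#' @param object A `trail_heatmap`.
#' @param trail Optional [trail_line()] overlaid as a dashed segment.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trail_heatmap <- function(object, trail = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                        fill = .data$probability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey10", high = "yellow",
                                 name = "passage\nprobability") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("Occupancy, %d ant(s)", object$n_ants)) +
    ggplot2::theme_minimal()
  if (!is.null(trail)) {
    p <- p + ggplot2::annotate("segment",
                               x = trail$p1[1], y = trail$p1[2],
                               xend = trail$p2[1], yend = trail$p2[2],
                               linetype = "dashed", colour = "white")
  }
  p
}

#' Plot a trajectory over the arena
#'
#' @param traj Trajectory tibble (`x_mm`, `y_mm`, `valid`, and `on_trail`
#'   if available).
#' @param arena An [arena_config()].
#' @param trail Optional [trail_line()] overlay.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, arena, trail = NULL) {
  df <- dplyr::filter(traj, .data$valid)
  aes_col <- if ("on_trail" %in% names(df)) {
    ggplot2::aes(.data$x_mm, .data$y_mm, colour = .data$on_trail)
  } else {
    ggplot2::aes(.data$x_mm, .data$y_mm)
  }
  p <- ggplot2::ggplot(df, aes_col) +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_y_reverse(limits = c(arena$height_mm, 0)) +
    ggplot2::scale_x_continuous(limits = c(0, arena$width_mm)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(trail)) {
    p <- p + ggplot2::annotate("segment",
                               x = trail$p1[1], y = trail$p1[2],
                               xend = trail$p2[1], yend = trail$p2[2],
                               linetype = "dashed", colour = "grey40")
  }
  p
}

#' Dose-response plot of group walking distances
#'
#' Mean with standard-error bars of the on-trail walked distance per group,
#' individual ants as jittered points, annotated with Dunnett star codes
#' when a `trail_dunnett` result is supplied.
#'
#' @param data Group data tibble (`group`, `y_mm`).
#' @param dunnett Optional `trail_dunnett` result for star annotations.
#' @param group,response Column names.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(data, dunnett = NULL, group = "group",
                               response = "y_mm") {
  df <- tibble::tibble(group = factor(data[[group]]), y = data[[response]])
  summ <- df |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean = mean(.data$y),
                     sem = sd(.data$y) / sqrt(dplyr::n()), .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_jitter(data = df, ggplot2::aes(.data$group, .data$y),
                         width = 0.15, alpha = 0.4, size = 0.8,
                         inherit.aes = FALSE) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::labs(x = NULL, y = "distance walked on trail (mm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(dunnett)) {
    ann <- dplyr::filter(tidy(dunnett), .data$stars != "ns")
    if (nrow(ann) > 0) {
      ymax <- max(df$y)
      p <- p + ggplot2::annotate("text", x = ann$group, y = ymax * 1.05,
                                 label = ann$stars)
    }
  }
  p
}
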