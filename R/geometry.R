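#' Distance from points to the trail segment
#'
#' Euclidean distance from each point to the closest point of the closed
#' segment between the trail endpoints. The segment is endpoint-capped: for
#' points beyond an endpoint the distance is measured to that endpoint, since
#' the applied trail is finite on the sheet.
#'
#' @param x,y Numeric vectors of point coordinates in arena millimetres.
#' @param trail A [trail_line()].
#' @return Numeric vector of distances in millimetres (`NA` where `x` or `y`
#'   is `NA`).
#' @examples
#' tl <- trail_line(c(0, 0), c(100, 0))
#' point_segment_distance(50, 5, tl)   # perpendicular: 5
#' point_segment_distance(c(-3, 103), c(4, 4), trail_line(c(0, 0), c(100, 0)))
#' @export
point_segment_distance <- function(x, y, trail) {
  stopifnot(inherits(trail, "trail_line"), length(x) == length(y))
  vx <- trail$p2[1] - trail$p1[1]
  vy <- trail$p2[2] - trail$p1[2]
  len2 <- vx^2 + vy^2
  t <- ((x - trail$p1[1]) * vx + (y - trail$p1[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (trail$p1[1] + t * vx))^2 + (y - (trail$p1[2] + t * vy))^2)
}

# nearest point on the closed segment, used by the walk simulator
nearest_trail_point <- function(x, y, trail) {
  vx <- trail$p2[1] - trail$p1[1]
  vy <- trail$p2[2] - trail$p1[2]
  len2 <- vx^2 + vy^2
  t <- ((x - trail$p1[1]) * vx + (y - trail$p1[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  cbind(trail$p1[1] + t * vx, trail$p1[2] + t * vy)
}

# area of the strip {q : dist(q, segment) < r} clipped to the arena,
# by exhaustive midpoint integration on a fine grid; used as the geometric
# reference for the uniform-exploration check of the walk simulator
trail_band_area_fraction <- function(trail, arena, r, cell = 0.25) {
  xs <- seq(cell / 2, arena$width_mm - cell / 2, by = cell)
  ys <- seq(cell / 2, arena$height_mm - cell / 2, by = cell)
  g <- expand.grid(x = xs, y = ys)
  inside <- point_segment_distance(g$x, g$y, trail) < r
  mean(inside)
}
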