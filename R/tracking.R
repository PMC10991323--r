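#' Estimate the static background frame
#'
#' Per-pixel temporal median over the stack (subsampled to at most
#' `max_frames` evenly spaced frames for long recordings). With a single
#' moving ant, each pixel is ant-free in well over half the frames, so the
#' median recovers the static scene — paper, trail line and illumination —
#' which then cancels in background subtraction.
#'
#' @param video An `ant_video` with at least 3 frames.
#' @param max_frames Cap on the number of frames entering the median
#'   (evenly spaced subsample).
#' @return Numeric matrix, the background frame.
#' @export
estimate_background <- function(video, max_frames = 101) {
  stopifnot(inherits(video, "ant_video"))
  n <- video$n_frames
  if (n < 3) {
    abort("background estimation needs at least 3 frames", class = "anttrail_input_error")
  }
  idx <- if (n > max_frames) unique(round(seq(1, n, length.out = max_frames))) else seq_len(n)
  m <- matrix(video$frames[, , idx], nrow = video$height_px * video$width_px)
  med <- apply(m, 1, median)
  matrix(med, video$height_px, video$width_px)
}

#' Segment the ant in one frame by background subtraction
#'
#' Thresholds the difference image `background - frame` at
#' `threshold_offset`, labels connected components (8-connectivity), keeps
#' components with area in `[min_area_px, max_area_px]`, and returns the
#' intensity-weighted centroid of the largest candidate in arena millimetres.
#' Ties on area are broken by the larger summed difference intensity. If no
#' candidate survives, the detection is flagged invalid.
#'
#' @param frame,background Numeric matrices of equal dimension.
#' @param p A [seg_params()].
#' @param mm_per_px Calibration of the (binned) frame.
#' @param trail Optional [trail_line()]; with
#'   `p$line_mask_halfwidth_mm > 0`, pixels near the line are excluded from
#'   the foreground mask.
#' @return One-row tibble: `x_mm`, `y_mm`, `area_px`, `valid`.
#' @export
segment_ant <- function(frame, background, p = seg_params(), mm_per_px = 1,
                        trail = NULL) {
  if (!all(dim(frame) == dim(background))) {
    abort("frame and background dimensions differ", class = "anttrail_input_error")
  }
  d <- background - frame
  mask <- d > p$threshold_offset
  if (!is.null(trail) && p$line_mask_halfwidth_mm > 0) {
    mask <- mask & !line_mask(dim(frame), mm_per_px, trail, p$line_mask_halfwidth_mm)
  }
  idx <- which(mask)
  if (length(idx) == 0) return(invalid_detection())

  lab <- label_components_8(idx, nrow(frame))
  best <- NULL
  for (comp in split(idx, lab)) {
    area <- length(comp)
    if (area < p$min_area_px || area > p$max_area_px) next
    wsum <- sum(d[comp])
    if (is.null(best) || area > best$area ||
        (area == best$area && wsum > best$wsum)) {
      best <- list(px = comp, area = area, wsum = wsum)
    }
  }
  if (is.null(best)) return(invalid_detection())

  h <- nrow(frame)
  r <- (best$px - 1) %% h + 1
  c <- (best$px - 1) %/% h + 1
  wts <- d[best$px]
  cr <- sum(r * wts) / sum(wts)
  cc <- sum(c * wts) / sum(wts)
  tibble::tibble(
    x_mm = (cc - 0.5) * mm_per_px,
    y_mm = (cr - 0.5) * mm_per_px,
    area_px = best$area,
    valid = TRUE
  )
}

invalid_detection <- function() {
  tibble::tibble(x_mm = NA_real_, y_mm = NA_real_, area_px = 0L, valid = FALSE)
}

# 8-connected component labels for a set of linear pixel indices
# (column-major, matrix with h rows); uses igraph over the adjacency list
label_components_8 <- function(idx, h) {
  n <- length(idx)
  if (n == 1) return(1L)
  # neighbour offsets down, right, down-right, up-right: each unordered
  # 8-neighbour pair appears exactly once
  r <- (idx - 1) %% h + 1
  offs <- list(
    dn = ifelse(r < h, idx + 1, NA),
    rt = idx + h,
    dr = ifelse(r < h, idx + h + 1, NA),
    ur = ifelse(r > 1, idx + h - 1, NA)
  )
  edges <- integer(0)
  for (o in offs) {
    j <- match(o, idx)
    has <- !is.na(j)
    if (any(has)) edges <- c(edges, rbind(which(has), j[has]))
  }
  if (length(edges) == 0) return(seq_len(n))
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  igraph::components(g)$membership
}

line_mask <- function(dims, mm_per_px, trail, halfwidth_mm) {
  xs <- (seq_len(dims[2]) - 0.5) * mm_per_px
  ys <- (seq_len(dims[1]) - 0.5) * mm_per_px
  g <- expand.grid(y = ys, x = xs)
  matrix(point_segment_distance(g$x, g$y, trail) < halfwidth_mm, dims[1], dims[2])
}

#' Detect the ant in every frame of a (binned) video
#'
#' Runs [estimate_background()] (unless a background is supplied) and
#' [segment_ant()] frame by frame.
#'
#' @param video An `ant_video`, normally the output of [bin_video()].
#' @param p A [seg_params()].
#' @param trail Optional [trail_line()] for the line mask.
#' @param background Optional precomputed background matrix.
#' @return Tibble of detections: `frame`, `x_mm`, `y_mm`, `area_px`, `valid`.
#' @export
track_video <- function(video, p = seg_params(), trail = NULL, background = NULL) {
  stopifnot(inherits(video, "ant_video"))
  bg <- background %||% estimate_background(video)
  det <- vector("list", video$n_frames)
  for (i in seq_len(video$n_frames)) {
    det[[i]] <- segment_ant(video$frames[, , i], bg, p,
                            mm_per_px = video$mm_per_px, trail = trail)
  }
  out <- dplyr::bind_rows(det)
  out$frame <- seq_len(video$n_frames)
  dplyr::relocate(out, "frame")
}

#' Assemble a gap-tolerant trajectory from per-frame detections
#'
#' Interior runs of invalid detections no longer than `max_gap_frames` are
#' filled by linear interpolation between the flanking valid centroids and
#' marked both valid and interpolated; longer runs stay invalid and
#' contribute no walked distance. Leading and trailing invalid frames are
#' never interpolated.
#'
#' @param detections Tibble from [track_video()], ordered by `frame`.
#' @param p A [seg_params()] (supplies `max_gap_frames`).
#' @param frame_period_ms Sampling period of the detections, milliseconds.
#' @return A tibble of class `ant_trajectory`: `frame`, `t_s`, `x_mm`,
#'   `y_mm`, `valid`, `interpolated`.
#' @export
build_trajectory <- function(detections, p = seg_params(), frame_period_ms = 160) {
  stopifnot(all(diff(detections$frame) > 0))
  if (!any(detections$valid)) {
    abort("no valid detections: empty trajectory", class = "anttrail_empty_trajectory")
  }
  x <- detections$x_mm; y <- detections$y_mm
  valid <- detections$valid
  interp <- rep(FALSE, length(valid))

  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) next
    if (k == 1 || k == length(runs$values)) next           # leading/trailing
    if (runs$lengths[k] > p$max_gap_frames) next
    i0 <- starts[k] - 1; i1 <- ends[k] + 1
    f <- seq_len(runs$lengths[k]) / (runs$lengths[k] + 1)
    gap <- starts[k]:ends[k]
    x[gap] <- x[i0] + f * (x[i1] - x[i0])
    y[gap] <- y[i0] + f * (y[i1] - y[i0])
    valid[gap] <- TRUE
    interp[gap] <- TRUE
  }
  out <- tibble::tibble(
    frame = detections$frame,
    t_s = (detections$frame - 1) * frame_period_ms / 1000,
    x_mm = x, y_mm = y, valid = valid, interpolated = interp
  )
  attr(out, "frame_period_ms") <- frame_period_ms
  class(out) <- c("ant_trajectory", class(out))
  out
}
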