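#' Render a trajectory as synthetic grayscale video frames
#'
#' Draws one frame per trajectory sample: a uniform light background crossed
#' by the grey trail line, with the ant as a dark anti-aliased ellipse centred
#' on the true position and aligned with the true heading. Rows with missing
#' coordinates render the background-plus-line template only. Optional
#' additive Gaussian noise is applied last.
#'
#' @param traj A trajectory tibble with `x_mm`, `y_mm` (and optionally
#'   `heading`) columns; positions must lie inside the arena.
#' @param arena An [arena_config()].
#' @param rp A [render_params()].
#' @param trail A [trail_line()] to draw, or `NULL` for a blank background.
#' @param dim_px Optional `c(height, width)` frame size; must equal the size
#'   implied by the arena geometry and calibration (it exists only as a
#'   consistency check against an externally imposed resolution).
#' @return An `ant_video` object (list with a `frames` array of dimension
#'   height x width x n and calibration metadata).
#' @export
render_frames <- function(traj, arena, rp = render_params(), trail = NULL,
                          dim_px = NULL) {
  stopifnot(inherits(arena, "arena_config"), inherits(rp, "render_params"))
  h <- round(arena$height_mm * arena$px_per_mm)
  w <- round(arena$width_mm * arena$px_per_mm)
  if (!is.null(dim_px) && !(dim_px[1] == h && dim_px[2] == w)) {
    abort(sprintf(
      "requested %d x %d frame does not match arena geometry (%d x %d at %g px/mm)",
      dim_px[1], dim_px[2], h, w, arena$px_per_mm
    ), class = "anttrail_config_error")
  }
  ok <- is.finite(traj$x_mm) & is.finite(traj$y_mm)
  if (any(traj$x_mm[ok] < 0 | traj$x_mm[ok] > arena$width_mm |
            traj$y_mm[ok] < 0 | traj$y_mm[ok] > arena$height_mm)) {
    abort("trajectory positions outside the arena", class = "anttrail_geometry_error")
  }

  template <- render_template(arena, rp, trail)
  n <- nrow(traj)
  frames <- array(template, dim = c(h, w, n))

  ppm <- arena$px_per_mm
  a <- rp$ant_length_mm / 2
  b <- a * rp$ant_aspect
  pad <- ceiling((a + 1.5 / ppm) * ppm)           # patch half-size in px
  edge <- (1 / ppm) / b                           # ~1 px anti-aliasing edge,
                                                  # in normalised ellipse units
  heading <- if ("heading" %in% names(traj)) traj$heading else
    infer_heading(traj$x_mm, traj$y_mm)

  for (i in seq_len(n)) {
    if (!ok[i]) next
    cx <- traj$x_mm[i] * ppm + 0.5                # mm -> 1-based px centre coords
    cy <- traj$y_mm[i] * ppm + 0.5
    cols <- max(1, floor(cx - pad)):min(w, ceiling(cx + pad))
    rows <- max(1, floor(cy - pad)):min(h, ceiling(cy + pad))
    # local mm offsets of the patch pixel centres from the ant centre
    dx <- (cols - cx) / ppm
    dy <- (rows - cy) / ppm
    ct <- cos(heading[i]); st <- sin(heading[i])
    u <- outer(dy, dx, function(Y, X) (X * ct + Y * st) / a)
    v <- outer(dy, dx, function(Y, X) (-X * st + Y * ct) / b)
    e <- sqrt(u^2 + v^2)
    cov <- pmin(1, pmax(0, (1 - e) / edge + 0.5))
    patch <- frames[rows, cols, i]
    frames[rows, cols, i] <- cov * rp$ant_intensity + (1 - cov) * patch
  }
  if (rp$noise_sd > 0) {
    frames <- frames + array(rnorm(length(frames), 0, rp$noise_sd), dim = dim(frames))
    frames[frames < 0] <- 0
    frames[frames > 1] <- 1
  }
  new_ant_video(frames, arena$frame_rate_hz, arena$px_per_mm)
}

#' Background-plus-line template frame
#'
#' @inheritParams render_frames
#' @return Numeric matrix (height x width) of grayscale intensities.
#' @export
render_template <- function(arena, rp = render_params(), trail = NULL) {
  h <- round(arena$height_mm * arena$px_per_mm)
  w <- round(arena$width_mm * arena$px_per_mm)
  template <- matrix(rp$background_intensity, h, w)
  if (!is.null(trail) && rp$line_halfwidth_mm > 0) {
    ppm <- arena$px_per_mm
    xs <- ((seq_len(w)) - 0.5) / ppm
    ys <- ((seq_len(h)) - 0.5) / ppm
    g <- expand.grid(y = ys, x = xs)
    d <- point_segment_distance(g$x, g$y, trail)
    covl <- pmin(1, pmax(0, (rp$line_halfwidth_mm - d) * ppm + 0.5))
    template <- matrix(
      covl * rp$line_intensity + (1 - covl) * rp$background_intensity, h, w
    )
  }
  template
}

infer_heading <- function(x, y) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  dx <- c(diff(x), 0); dy <- c(diff(y), 0)
  th <- atan2(dy, dx)
  th[n] <- th[n - 1]
  still <- c(dx[-n] == 0 & dy[-n] == 0, FALSE)
  for (i in which(still)) if (i > 1) th[i] <- th[i - 1]
  th
}

new_ant_video <- function(frames, frame_rate_hz, px_per_mm,
                          spatial_factor = 1L, temporal_factor = 1L) {
  structure(
    list(
      frames = frames,
      height_px = dim(frames)[1], width_px = dim(frames)[2],
      n_frames = dim(frames)[3],
      frame_rate_hz = frame_rate_hz,
      px_per_mm = px_per_mm,
      spatial_factor = as.integer(spatial_factor),
      temporal_factor = as.integer(temporal_factor),
      mm_per_px = spatial_factor / px_per_mm,
      frame_period_ms = 1000 * temporal_factor / frame_rate_hz
    ),
    class = "ant_video"
  )
}

#' @export
print.ant_video <- function(x, ...) {
  cat(sprintf(
    "<ant_video> %d frames of %d x %d px, %g ms/frame, %.3g mm/px (binned %dx, %dx)\n",
    x$n_frames, x$height_px, x$width_px, x$frame_period_ms, x$mm_per_px,
    x$spatial_factor, x$temporal_factor
  ))
  invisible(x)
}

#' Write video frames as a numbered image sequence
#'
#' @param video An `ant_video`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @param format `"png"` or `"tiff"` (both lossless).
#' @return Invisibly, the vector of file paths written.
#' @export
write_frames <- function(video, dir, prefix = "frame", format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- video$n_frames
  paths <- file.path(dir, sprintf("%s_%05d.%s", prefix, seq_len(n), format))
  for (i in seq_len(n)) {
    if (format == "png") {
      png::writePNG(video$frames[, , i], paths[i])
    } else {
      tiff::writeTIFF(video$frames[, , i], paths[i])
    }
  }
  invisible(paths)
}

#' Read a grayscale frame stack
#'
#' Reads a numbered PNG/TIFF image sequence (a directory or an explicit
#' vector of file paths, taken in sorted order) into an `ant_video`. Colour
#' input is converted to luminance with the standard Rec. 709 weights.
#'
#' @param source Directory containing the sequence, or a character vector of
#'   image paths.
#' @param frame_rate_hz,px_per_mm Acquisition metadata (not stored in the
#'   image files).
#' @return An `ant_video`.
#' @export
read_frames <- function(source, frame_rate_hz = 25, px_per_mm = 4) {
  paths <- if (length(source) == 1 && dir.exists(source)) {
    sort(list.files(source, pattern = "\\.(png|tif|tiff)$", full.names = TRUE,
                    ignore.case = TRUE))
  } else {
    source
  }
  if (length(paths) == 0 || !all(file.exists(paths))) {
    abort(sprintf("no readable frames in source: %s", toString(utils::head(source, 3))),
          class = "anttrail_input_error")
  }
  read1 <- function(p) {
    img <- if (grepl("\\.png$", p, ignore.case = TRUE)) {
      png::readPNG(p)
    } else {
      tiff::readTIFF(p)
    }
    to_luminance(img)
  }
  first <- read1(paths[1])
  frames <- array(0, dim = c(nrow(first), ncol(first), length(paths)))
  frames[, , 1] <- first
  if (length(paths) > 1) {
    for (i in 2:length(paths)) {
      f <- read1(paths[i])
      if (!all(dim(f) == dim(first))) {
        abort(sprintf("frame %s has mismatched dimensions", paths[i]),
              class = "anttrail_input_error")
      }
      frames[, , i] <- f
    }
  }
  new_ant_video(frames, frame_rate_hz, px_per_mm)
}

to_luminance <- function(img) {
  if (length(dim(img)) == 2) return(img)
  if (dim(img)[3] >= 3) {
    0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  } else {
    img[, , 1]
  }
}
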