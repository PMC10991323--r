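#' Spatio-temporal video binning
#'
#' Compresses a frame stack by averaging non-overlapping
#' `spatial_factor x spatial_factor` pixel blocks and runs of
#' `temporal_factor` consecutive frames, the compression applied before
#' tracking (4 x 4 pixels and 4 frames by default, i.e. 160 ms per binned
#' frame at 25 Hz). The bin statistic is the arithmetic mean, so intensity
#' scale — and hence segmentation thresholds — are resolution-independent.
#' Trailing rows, columns or frames that do not fill a bin are dropped
#' (floor semantics).
#'
#' @param video An `ant_video`.
#' @param spatial_factor,temporal_factor Positive integer binning factors.
#' @return A binned `ant_video` with updated `mm_per_px` and
#'   `frame_period_ms` calibration.
#' @examples
#' \dontrun{
#' bv <- bin_video(v, 4, 4)   # 25 Hz input -> bv$frame_period_ms == 160
#' }
#' @export
bin_video <- function(video, spatial_factor = 4, temporal_factor = 4) {
  stopifnot(inherits(video, "ant_video"))
  sf <- as.integer(spatial_factor); tf <- as.integer(temporal_factor)
  if (is.na(sf) || is.na(tf) || sf < 1 || tf < 1) {
    abort("binning factors must be integers >= 1", class = "anttrail_parameter_error")
  }
  h <- video$height_px; w <- video$width_px; n <- video$n_frames
  hb <- h %/% sf; wb <- w %/% sf; nb <- n %/% tf
  if (hb < 1 || wb < 1 || nb < 1) {
    abort("binning factors exceed the stack dimensions", class = "anttrail_parameter_error")
  }

  out <- array(0, dim = c(hb, wb, nb))
  for (t in seq_len(nb)) {
    fr <- video$frames[seq_len(hb * sf), seq_len(wb * sf), (t - 1) * tf + 1]
    if (tf > 1) {
      for (j in 2:tf) {
        fr <- fr + video$frames[seq_len(hb * sf), seq_len(wb * sf), (t - 1) * tf + j]
      }
      fr <- fr / tf
    }
    out[, , t] <- bin_matrix(fr, sf, hb, wb)
  }
  new_ant_video(out, video$frame_rate_hz, video$px_per_mm,
                spatial_factor = video$spatial_factor * sf,
                temporal_factor = video$temporal_factor * tf)
}

# block-mean a (hb*sf) x (wb*sf) matrix down to hb x wb
bin_matrix <- function(m, sf, hb, wb) {
  if (sf == 1) return(m)
  dim(m) <- c(sf, hb * wb * sf)
  m <- colSums(m)                       # sum within column blocks of rows
  dim(m) <- c(hb, wb * sf)
  m <- t(m)
  dim(m) <- c(sf, wb * hb)
  m <- colSums(m)
  dim(m) <- c(wb, hb)
  t(m) / sf^2
}

# binned pixel centre (row r, col c, 1-based) in arena mm
binned_px_to_mm <- function(r, c, video) {
  list(
    x_mm = (c - 0.5) * video$mm_per_px,
    y_mm = (r - 0.5) * video$mm_per_px
  )
}
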