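# Shared fixtures: a reduced-resolution arena (2 px/mm, so binned pixels are
# 2 mm) keeps rendering and tracking fast while exercising the same code
# paths as full-resolution recordings.

test_arena <- function(duration_s = 10) {
  arena_config(width_mm = 160, height_mm = 90, px_per_mm = 2,
               frame_rate_hz = 25, duration_s = duration_s)
}

test_trail <- function() trail_line(c(10, 45), c(150, 45))

# per-bin mean of the ground-truth positions: the true position represented
# by one temporally binned (motion-averaged) frame
bin_truth <- function(traj, tf, nb) {
  list(
    x = colMeans(matrix(traj$x_mm[seq_len(tf * nb)], tf)),
    y = colMeans(matrix(traj$y_mm[seq_len(tf * nb)], tf))
  )
}

# render -> bin -> track -> trajectory for one simulated ant
track_synthetic <- function(traj, arena, trail, rp = render_params(),
                            p = seg_params()) {
  v <- render_frames(traj, arena, rp, trail)
  bv <- bin_video(v, 4, 4)
  det <- track_video(bv, p)
  build_trajectory(det, p, bv$frame_period_ms)
}
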