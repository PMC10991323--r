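# background estimation, segmentation and trajectory assembly

test_that("a static scene is its own background; tiny stacks are rejected", {
  frame <- matrix(runif(100), 10, 10)
  v <- anttrail:::new_ant_video(array(frame, c(10, 10, 5)), 25, 2)
  bg <- estimate_background(v)
  expect_equal(bg, frame)
  v1 <- anttrail:::new_ant_video(array(frame, c(10, 10, 2)), 25, 2)
  expect_error(estimate_background(v1), class = "anttrail_input_error")
})

test_that("a moving blob visiting each pixel in a minority of frames vanishes", {
  set.seed(1)
  base <- matrix(0.8, 12, 12)
  n <- 9
  frames <- array(base, c(12, 12, n))
  for (i in seq_len(n)) frames[((i - 1) %% 12) + 1, , i] <- 0.1  # one dark row per frame
  v <- anttrail:::new_ant_video(frames, 25, 2)
  bg <- estimate_background(v)
  # brute-force per-pixel median oracle
  oracle <- apply(matrix(frames, 144, n), 1, median)
  expect_equal(as.vector(bg), oracle)
  expect_true(all(bg == 0.8))
})

test_that("a frame identical to background yields no detection", {
  bg <- matrix(0.8, 10, 10)
  det <- segment_ant(bg, bg, seg_params(), mm_per_px = 1)
  expect_false(det$valid)
})

test_that("segmentation centroid matches an exhaustive weighted-centroid oracle", {
  bg <- matrix(0.8, 30, 40)
  frame <- bg
  # smooth dark disk centred between pixels
  cx <- 21.3; cy <- 14.7
  for (r in 10:20) for (c in 16:27) {
    d <- sqrt((r - cy)^2 + (c - cx)^2)
    if (d < 4) frame[r, c] <- 0.8 - 0.6 * (1 - d / 4)
  }
  det <- segment_ant(frame, bg, seg_params(threshold_offset = 0.05), mm_per_px = 2)
  diff <- bg - frame
  idx <- which(diff > 0.05)
  r <- (idx - 1) %% 30 + 1; c <- (idx - 1) %/% 30 + 1
  w <- diff[idx]
  expect_true(det$valid)
  expect_lt(abs(det$x_mm / 2 + 0.5 - sum(c * w) / sum(w)), 1e-9)
  expect_lt(abs(det$y_mm / 2 + 0.5 - sum(r * w) / sum(w)), 1e-9)
})

test_that("the largest-area candidate wins; diagonal pixels are one component", {
  bg <- matrix(0.9, 20, 20)
  frame <- bg
  frame[3:5, 3:5] <- 0.1            # area 9
  frame[12:13, 12:13] <- 0.1        # area 4
  det <- segment_ant(frame, bg, seg_params(), mm_per_px = 1)
  expect_equal(det$area_px, 9L)
  expect_lt(abs(det$x_mm - 3.5), 1e-9)   # centroid of cols 3:5 -> 4 - 0.5

  # an 8-connected diagonal chain is a single component
  frame2 <- bg
  frame2[cbind(5:9, 5:9)] <- 0.1
  det2 <- segment_ant(frame2, bg, seg_params(), mm_per_px = 1)
  expect_true(det2$valid)
  expect_equal(det2$area_px, 5L)
})

test_that("area limits filter candidates", {
  bg <- matrix(0.9, 20, 20)
  frame <- bg
  frame[3:12, 3:12] <- 0.1          # area 100
  det <- segment_ant(frame, bg, seg_params(max_area_px = 50), mm_per_px = 1)
  expect_false(det$valid)
  det2 <- segment_ant(frame, bg, seg_params(min_area_px = 101), mm_per_px = 1)
  expect_false(det2$valid)
})

test_that("segmentation is translation-equivariant", {
  bg <- matrix(0.85, 25, 25)
  mk <- function(r0, c0) {
    f <- bg
    f[r0 + 0:2, c0 + 0:2] <- 0.2
    f
  }
  d1 <- segment_ant(mk(5, 5), bg, seg_params(), mm_per_px = 1)
  d2 <- segment_ant(mk(12, 9), bg, seg_params(), mm_per_px = 1)
  expect_equal(d2$x_mm - d1$x_mm, 4)
  expect_equal(d2$y_mm - d1$y_mm, 7)
})

test_that("mismatched frame and background dimensions are rejected", {
  expect_error(segment_ant(matrix(0, 5, 5), matrix(0, 6, 5), seg_params()),
               class = "anttrail_input_error")
})

test_that("short gaps are linearly interpolated, long ones stay invalid", {
  p <- seg_params(max_gap_frames = 3)
  det <- tibble::tibble(
    frame = 1:9,
    x_mm = c(0, NA, 2, NA, NA, NA, NA, 7, 8),
    y_mm = c(0, NA, 2, NA, NA, NA, NA, 7, 8),
    area_px = 5L,
    valid = !is.na(x_mm)
  )
  tr <- build_trajectory(det, p, frame_period_ms = 160)
  expect_equal(tr$x_mm[2], 1)                     # midpoint of (0,0)-(2,2)
  expect_true(tr$valid[2] && tr$interpolated[2])
  expect_false(any(tr$valid[4:7]))                # gap of 4 > max_gap_frames
  expect_false(any(tr$interpolated[c(1, 3, 8, 9)]))
})

test_that("leading and trailing gaps are never interpolated", {
  p <- seg_params(max_gap_frames = 5)
  det <- tibble::tibble(
    frame = 1:6,
    x_mm = c(NA, NA, 3, 4, NA, NA), y_mm = c(NA, NA, 3, 4, NA, NA),
    area_px = 5L, valid = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  )
  tr <- build_trajectory(det, p, 160)
  expect_equal(tr$valid, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
})

test_that("an all-invalid detection table is an empty-trajectory error", {
  det <- tibble::tibble(frame = 1:4, x_mm = NA_real_, y_mm = NA_real_,
                        area_px = 0L, valid = FALSE)
  expect_error(build_trajectory(det, seg_params(), 160),
               class = "anttrail_empty_trajectory")
})

test_that("noise-free synthetic renders are tracked with sub-pixel error", {
  arena <- test_arena(10)
  tl <- test_trail()
  traj <- simulate_trajectory(walk_params(trail_attraction = 0.3, seed = 21),
                              arena, tl)
  tr <- track_synthetic(traj, arena, tl)
  expect_equal(mean(tr$valid), 1)
  truth <- bin_truth(traj, 4, nrow(tr))
  rmse <- sqrt(mean((tr$x_mm - truth$x)^2 + (tr$y_mm - truth$y)^2))
  expect_lt(rmse, 2)   # one binned pixel = 2 mm at this calibration
})

test_that("moderate pixel noise still yields near-complete detection", {
  arena <- test_arena(10)
  tl <- test_trail()
  traj <- simulate_trajectory(walk_params(trail_attraction = 0.3, seed = 22),
                              arena, tl)
  set.seed(22)
  tr <- track_synthetic(traj, arena, tl, rp = render_params(noise_sd = 0.05))
  expect_gte(mean(tr$valid), 0.99)
  truth <- bin_truth(traj, 4, nrow(tr))
  rmse <- sqrt(mean(((tr$x_mm - truth$x)^2 + (tr$y_mm - truth$y)^2)[tr$valid]))
  expect_lt(rmse, 4)   # two binned pixels under noise
})
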