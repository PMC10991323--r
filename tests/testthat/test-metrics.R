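# on-trail classification, walked distance, occupancy heatmaps

traj_from_points <- function(x, y, valid = TRUE, period_ms = 160) {
  n <- length(x)
  out <- tibble::tibble(
    frame = seq_len(n), t_s = (seq_len(n) - 1) * period_ms / 1000,
    x_mm = x, y_mm = y, valid = rep_len(valid, n)
  )
  attr(out, "frame_period_ms") <- period_ms
  out
}

test_that("the 5 mm rule is strict: a sample at exactly 5 mm is off-trail", {
  tl <- trail_line(c(0, 0), c(100, 0))
  tr <- traj_from_points(c(10, 20, 30), c(5, 4.999, 60))
  s <- on_trail_series(tr, tl)
  expect_equal(s$on_trail, c(FALSE, TRUE, FALSE))
})

test_that("invalid samples are never on-trail; a trajectory on the line always is", {
  tl <- test_trail()
  tr <- traj_from_points(c(20, 30, 40), rep(45, 3), valid = c(TRUE, FALSE, TRUE))
  s <- on_trail_series(tr, tl)
  expect_equal(s$on_trail, c(TRUE, FALSE, TRUE))
  far <- traj_from_points(c(20, 30), c(0, 0))
  expect_false(any(on_trail_series(far, tl)$on_trail))
})

test_that("walked distances: full-on-trail, stationary and mixed cases", {
  tl <- trail_line(c(0, 0), c(100, 0))
  on <- traj_from_points(seq(0, 50, by = 10), rep(0, 6))
  m <- trail_distance(on, tl)
  expect_equal(m$on_trail_mm, m$total_path_mm)
  expect_equal(m$total_path_mm, 50)

  still <- traj_from_points(rep(30, 5), rep(20, 5))
  m0 <- trail_distance(still, tl)
  expect_equal(m0$total_path_mm, 0)
  expect_equal(m0$on_trail_mm, 0)
})

test_that("zig-zag crossing the band matches a step-enumeration oracle", {
  tl <- trail_line(c(0, 0), c(100, 0))
  # 11 samples alternating between 2 mm and 8 mm from the line
  x <- seq(0, 100, by = 10)
  y <- rep(c(2, 8), length.out = 11)
  tr <- traj_from_points(x, y)
  s <- on_trail_series(tr, tl)
  m <- trail_distance(s)

  # oracle: enumerate steps, credit those with both endpoints under 5 mm
  flags <- y < 5
  L <- sqrt(diff(x)^2 + diff(y)^2)
  expect_equal(m$total_path_mm, sum(L))
  expect_equal(m$on_trail_mm, sum(L[flags[-11] & flags[-1]]))
  expect_equal(m$on_trail_mm, 0)   # endpoints alternate, no step fully in-band

  # the permissive attribution rule credits every band-touching step
  m2 <- trail_distance(s, rule = "either")
  expect_equal(m2$on_trail_mm, sum(L[flags[-11] | flags[-1]]))
})

test_that("steps spanning invalid samples contribute no distance", {
  tl <- trail_line(c(0, 0), c(100, 0))
  tr <- traj_from_points(c(0, 10, 20, 30), rep(0, 4),
                         valid = c(TRUE, FALSE, TRUE, TRUE))
  m <- trail_distance(tr, tl)
  expect_equal(m$total_path_mm, 10)   # only the 20->30 step survives
})

test_that("on-trail distance never exceeds total and grows with the threshold", {
  tl <- test_trail()
  arena <- test_arena(30)
  for (s in 1:5) {
    traj <- simulate_trajectory(walk_params(trail_attraction = 0.2,
                                            seed = 200 + s), arena, tl)
    m5 <- trail_distance(on_trail_series(traj, tl, 5))
    m10 <- trail_distance(on_trail_series(traj, tl, 10))
    expect_lte(m5$on_trail_mm, m5$total_path_mm)
    expect_gte(m10$on_trail_mm, m5$on_trail_mm)
  }
})

test_that("metrics are invariant under joint rigid motion of path and trail", {
  arena <- test_arena(20)
  tl <- test_trail()
  traj <- simulate_trajectory(walk_params(trail_attraction = 0.3, seed = 31),
                              arena, tl)
  m0 <- trail_distance(on_trail_series(traj, tl))

  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  shift <- c(12, -5)
  rot <- function(x, y) cbind(x, y) %*% t(R) + rep(shift, each = length(x))
  p <- rot(traj$x_mm, traj$y_mm)
  traj2 <- traj
  traj2$x_mm <- p[, 1]; traj2$y_mm <- p[, 2]
  tl2 <- trail_line(rot(tl$p1[1], tl$p1[2]), rot(tl$p2[1], tl$p2[2]))
  m1 <- trail_distance(on_trail_series(traj2, tl2))
  expect_equal(m1$total_path_mm, m0$total_path_mm, tolerance = 1e-10)
  expect_equal(m1$on_trail_mm, m0$on_trail_mm, tolerance = 1e-10)
})

test_that("heatmaps count valid samples, add over ants, and conserve totals", {
  arena <- test_arena(5)
  still <- traj_from_points(rep(33, 7), rep(21, 7))
  h1 <- accumulate_heatmap(still, arena, cell_mm = 2)
  expect_equal(sum(h1$counts), 7)
  expect_equal(max(h1$counts), 7)   # a single occupied cell

  other <- traj_from_points(c(10, 12, 14), c(50, 50, 50))
  both <- dplyr::bind_rows(
    dplyr::mutate(still, ant_id = "a"),
    dplyr::mutate(other, ant_id = "b")
  )
  hb <- accumulate_heatmap(both, arena, cell_mm = 2)
  h2 <- accumulate_heatmap(other, arena, cell_mm = 2)
  expect_equal(hb$counts, h1$counts + h2$counts)
  expect_equal(sum(hb$counts), 10)
  expect_equal(hb$n_ants, 2L)
})

test_that("cell-edge samples go to the higher-index cell; bad cell size errors", {
  arena <- test_arena(5)
  tr <- traj_from_points(4, 6)       # exactly on the x and y edges of cell (3,2)/(4,3)
  h <- accumulate_heatmap(tr, arena, cell_mm = 2)
  expect_equal(h$counts[4, 3], 1L)
  expect_error(accumulate_heatmap(tr, arena, cell_mm = 0),
               class = "anttrail_parameter_error")
})

test_that("heatmap tibble and plot interfaces work", {
  arena <- test_arena(5)
  tr <- traj_from_points(c(10, 30), c(10, 30))
  h <- accumulate_heatmap(tr, arena, 2)
  tb <- as_tibble(h)
  expect_equal(sum(tb$count), 2)
  expect_equal(sum(tb$probability), 1)
  expect_s3_class(autoplot(h, trail = test_trail()), "ggplot")
})
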