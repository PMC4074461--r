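test_that("COP reconstruction follows the moment balance over the corners", {
  mk <- function(f) raw_recording(t = 0:3 / 50,
                                  f_tl = rep(f[1], 4), f_tr = rep(f[2], 4),
                                  f_bl = rep(f[3], 4), f_br = rep(f[4], 4))
  # equal forces -> center
  traj <- compute_cop_series(mk(c(20, 20, 20, 20)))
  expect_equal(traj$x, rep(0, 4))
  expect_equal(traj$y, rep(0, 4))
  # all load on the top-right corner -> that corner's coordinates
  traj <- compute_cop_series(mk(c(0, 80, 0, 0)))
  expect_equal(traj$x, rep(22.5, 4))
  expect_equal(traj$y, rep(13.25, 4))
  # hand evaluation: f = (10, 30, 10, 30)
  traj <- compute_cop_series(mk(c(10, 30, 10, 30)))
  expect_equal(traj$x, rep(22.5 * (60 - 20) / 80, 4))
  expect_equal(traj$y, rep(0, 4))
})

test_that("COP is invariant to uniform force scaling and mirrors with the cells", {
  set.seed(11)
  f <- matrix(runif(40, 5, 30), 10, 4)
  t <- (0:9) / 50
  rec1 <- raw_recording(t, f[, 1], f[, 2], f[, 3], f[, 4])
  rec2 <- raw_recording(t, 7.3 * f[, 1], 7.3 * f[, 2], 7.3 * f[, 3],
                        7.3 * f[, 4])
  t1 <- compute_cop_series(rec1); t2 <- compute_cop_series(rec2)
  expect_equal(t1$x, t2$x, tolerance = 1e-12)
  expect_equal(t1$y, t2$y, tolerance = 1e-12)
  # swap left and right cell pairs: x negated, y preserved
  recm <- raw_recording(t, f[, 2], f[, 1], f[, 4], f[, 3])
  tm <- compute_cop_series(recm)
  expect_equal(tm$x, -t1$x, tolerance = 1e-12)
  expect_equal(tm$y, t1$y, tolerance = 1e-12)
})

test_that("forces_from_cop round-trips random in-bounds trajectories to 1e-9 cm", {
  set.seed(42)
  n <- 200
  traj <- cop_trajectory(runif(n, -20, 20), runif(n, -12, 12), fs = 50)
  rec <- forces_from_cop(traj, load_series = runif(n, 50, 70))
  back <- compute_cop_series(rec)
  expect_lt(max(abs(back$x - traj$x)), 1e-9)
  expect_lt(max(abs(back$y - traj$y)), 1e-9)
  # corner decompositions from the trivial cases
  center <- forces_from_cop(cop_trajectory(c(0, 0), c(0, 0), fs = 50),
                            load_series = 80)
  expect_equal(unlist(center$samples[1, -1], use.names = FALSE),
               rep(20, 4))
  corner <- forces_from_cop(cop_trajectory(c(22.5, 22.5), c(13.25, 13.25),
                                           fs = 50), load_series = 80)
  expect_equal(unlist(corner$samples[1, -1], use.names = FALSE),
               c(0, 80, 0, 0))
})

test_that("low-load samples are interpolated and edge runs dropped", {
  # sample 3 carries almost no load; samples 1 and 8 none at all
  f <- rep(20, 8)
  f_low <- c(0.0, 20, 0.1, 20, 20, 20, 20, 0.0)
  scale <- f_low / 20
  rec <- raw_recording(t = 0:7 / 50, f_tl = 10 * scale, f_tr = 30 * scale,
                       f_bl = 10 * scale, f_br = 30 * scale)
  traj <- compute_cop_series(rec)
  expect_equal(length(traj$x), 6)          # leading + trailing dropped
  expect_equal(attr(traj, "n_interpolated"), 1L)
  expect_equal(traj$x, rep(11.25, 6), tolerance = 1e-12)  # neighbours agree
})

test_that("degenerate inputs raise classed errors", {
  expect_error(
    compute_cop_series(raw_recording(t = 0:3 / 50, f_tl = rep(0, 4),
                                     f_tr = rep(0, 4), f_bl = rep(0, 4),
                                     f_br = rep(0, 4))),
    class = "swayboard_signal_error")
  expect_error(raw_recording(t = c(0, 0.02, 0.02), f_tl = 1:3, f_tr = 1:3,
                             f_bl = 1:3, f_br = 1:3),
               class = "swayboard_format_error")
  expect_error(raw_recording(t = 0:2 / 50, f_tl = c(1, -1, 1), f_tr = 1:3,
                             f_bl = 1:3, f_br = 1:3),
               class = "swayboard_format_error")
  out <- cop_trajectory(c(30, 30), c(0, 0), fs = 50)  # outside the board
  expect_error(forces_from_cop(out, load_series = 60),
               class = "swayboard_domain_error")
})
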