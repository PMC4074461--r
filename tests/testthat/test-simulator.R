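test_that("the OU sway generator honors its calibration contracts", {
  # noiseless limit: vanishing diffusion, vanishing path
  quiet <- simulate_cop_trajectory(sway_params(sigma_x = 1e-12,
                                               sigma_y = 1e-12,
                                               duration_s = 10), seed = 31)
  expect_lt(path_length(quiet), 1e-6)
  # exact target-path-length rescaling
  for (seed in c(1, 99)) {
    traj <- simulate_cop_trajectory(sway_params(target_pl_cm = 36),
                                    seed = seed)
    expect_equal(path_length(traj), 36, tolerance = 1e-9)
  }
  # determinism
  t1 <- simulate_cop_trajectory(sway_params(duration_s = 5), seed = 7)
  t2 <- simulate_cop_trajectory(sway_params(duration_s = 5), seed = 7)
  t3 <- simulate_cop_trajectory(sway_params(duration_s = 5), seed = 8)
  expect_identical(t1$x, t2$x)
  expect_false(identical(t1$x, t3$x))
  # points stay on the board
  g <- board_geometry()
  expect_true(all(abs(t1$x) <= g$width_x / 2))
  expect_true(all(abs(t1$y) <= g$depth_y / 2))
})

test_that("the default study design produces the full factorial trial table", {
  trials <- simulate_study(study_design(seed = 32))
  expect_equal(nrow(trials), 20 * 4 * 4 * 3)
  expect_setequal(unique(trials$session), c("A1", "B", "A2", "A3"))
  expect_setequal(unique(trials$task), c("STOE", "STCE", "SOOE", "SOCE"))
  expect_true(all(trials$pl_cm >= 0))
  # velocity is path length over task duration by construction
  dur <- c(STOE = 30, STCE = 30, SOOE = 10, SOCE = 10)
  expect_equal(trials$va_cm_s, trials$pl_cm / dur[trials$task],
               ignore_attr = TRUE)
  gt <- attr(trials, "ground_truth")
  expect_true(gt$true_icc > 0 && gt$true_icc < 1)
})

test_that("the same master seed reproduces the study byte-for-byte", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(simulate_study(study_design(n_subjects = 5, seed = 33)), f1,
            row.names = FALSE)
  write.csv(simulate_study(study_design(n_subjects = 5, seed = 33)), f2,
            row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a single large study recovers the design ICC", {
  d <- two_session_design(n = 500, seed = 34)
  m <- two_session_matrix(d)
  est <- icc_twoway(m, "agreement", "single")$icc
  expect_equal(est, d$true_icc, tolerance = 0.08)
})

test_that("ICC estimates converge to the truth as n grows", {
  # consistency of the estimator: average absolute bias shrinks with n
  bias_at <- function(n, reps, seed0) {
    mean(vapply(seq_len(reps), function(i) {
      m <- two_session_matrix(two_session_design(n, seed = seed0 + i))
      icc_twoway(m)$icc
    }, numeric(1))) - two_session_design(2)$true_icc
  }
  b50 <- abs(bias_at(50, 40, 3500))
  b500 <- abs(bias_at(500, 40, 4500))
  expect_lt(b500, 0.02)
  expect_lt(b500, b50 + 0.01)
})

test_that("the raw-recording route reproduces the table route", {
  dir <- tempfile("recs")
  d <- study_design(n_subjects = 2,
                    tasks = data.frame(task = "SOOE", duration_s = 10,
                                       mean_pl_cm = 44,
                                       stringsAsFactors = FALSE),
                    n_trials = 1, sessions = c("A1", "B"),
                    platform_sessions = character(0), seed = 36)
  trials <- simulate_study(d, recordings_dir = dir)
  expect_true(all(file.exists(trials$file)))
  spec <- filter_spec()
  for (j in seq_len(nrow(trials))) {
    rec <- read_raw_recording(trials$file[j])
    traj <- lowpass_filter(resample_uniform(compute_cop_series(rec),
                                            spec$fs_hz), spec)
    expect_equal(path_length(traj), trials$pl_cm[j],
                 tolerance = 0.02)  # route-consistency bound
  }
  unlink(dir, recursive = TRUE)
})
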