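#' Sway model parameters
#'
#' Parameters of the Ornstein-Uhlenbeck (OU) sway generator. The OU process
#' is mean-reverting diffusion — stationary, band-limited at low frequency,
#' and visually similar to quiet-stance COP wander, unlike white noise. Per
#' axis the discrete update is
#' \deqn{x_{t+1} = x_t - \theta x_t \Delta t + \sigma \sqrt{\Delta t}\,\epsilon_t,
#'       \quad \epsilon_t \sim N(0,1).}
#'
#' Defaults (theta 1/s, sigma 0.4 cm/sqrt(s), 30 s at 50 Hz) give raw path
#' lengths of the order of tens of cm — the range observed in quiet standing
#' — with a stationary sway amplitude of a few mm, far inside the board.
#'
#' @param theta mean-reversion rate, 1/s (> 0).
#' @param sigma_x,sigma_y diffusion scale per axis, cm/sqrt(s) (> 0).
#' @param duration_s trial duration, s.
#' @param fs_hz sampling rate, Hz.
#' @param target_pl_cm optional calibration target: the trajectory is
#'   rescaled about its mean so its path length equals this exactly.
#' @return Object of class `sway_params`.
#' @export
sway_params <- function(theta = 1, sigma_x = 0.4, sigma_y = 0.4,
                        duration_s = 30, fs_hz = 50, target_pl_cm = NULL) {
  stopifnot_number(theta, "theta", positive = TRUE)
  stopifnot_number(sigma_x, "sigma_x", positive = TRUE)
  stopifnot_number(sigma_y, "sigma_y", positive = TRUE)
  stopifnot_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_number(fs_hz, "fs_hz", positive = TRUE)
  if (duration_s * fs_hz < 2)
    abort_sb("duration_s * fs_hz must be >= 2", "swayboard_parameter_error")
  if (!is.null(target_pl_cm))
    stopifnot_number(target_pl_cm, "target_pl_cm", positive = TRUE)
  structure(list(theta = theta, sigma_x = sigma_x, sigma_y = sigma_y,
                 duration_s = duration_s, fs_hz = fs_hz,
                 target_pl_cm = target_pl_cm),
            class = "sway_params")
}

# one OU axis via the linear recursion x_{t+1} = (1 - theta dt) x_t + noise
ou_axis <- function(n, theta, sigma, dt) {
  noise <- sigma * sqrt(dt) * stats::rnorm(n - 1)
  c(0, stats::filter(noise, 1 - theta * dt, method = "recursive"))
}

#' Simulate a COP trajectory
#'
#' Draws an OU sway path per axis (see [sway_params()]), clips it to the
#' board rectangle, and — if `target_pl_cm` is set — rescales it about its
#' mean so [path_length()] of the result equals the target exactly (path
#' length is homogeneous of degree 1 under scaling about any fixed point).
#'
#' @param p a [sway_params()].
#' @param seed optional integer; fixed seed gives an identical trajectory.
#' @param geometry a [board_geometry()] used for clipping.
#' @param meta named list of identifiers carried on the trajectory.
#' @return A [cop_trajectory()] at `p$fs_hz`.
#' @examples
#' traj <- simulate_cop_trajectory(sway_params(target_pl_cm = 36), seed = 1)
#' path_length(traj)  # 36, exactly
#' @export
simulate_cop_trajectory <- function(p, seed = NULL,
                                    geometry = board_geometry(),
                                    meta = list()) {
  if (!inherits(p, "sway_params"))
    abort_sb("`p` must be a sway_params object", "swayboard_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(p$duration_s * p$fs_hz) + 1L
  dt <- 1 / p$fs_hz
  x <- ou_axis(n, p$theta, p$sigma_x, dt)
  y <- ou_axis(n, p$theta, p$sigma_y, dt)
  x <- pmin(pmax(x, -geometry$width_x / 2), geometry$width_x / 2)
  y <- pmin(pmax(y, -geometry$depth_y / 2), geometry$depth_y / 2)
  traj <- cop_trajectory(x, y, fs = p$fs_hz, t = (seq_len(n) - 1L) * dt,
                         geometry = geometry, meta = meta)
  if (!is.null(p$target_pl_cm)) {
    pl <- path_length(traj)
    if (pl <= 0)
      abort_sb("degenerate sway path: cannot rescale to a target path length",
               "swayboard_signal_error")
    s <- p$target_pl_cm / pl
    traj$x <- mean(traj$x) + s * (traj$x - mean(traj$x))
    traj$y <- mean(traj$y) + s * (traj$y - mean(traj$y))
  }
  traj
}

#' Multi-session reliability study design
#'
#' The design of a synthetic balance-reliability study: `n_subjects` subjects
#' perform each task `n_trials` times in each measurement session. The
#' default layout is the canonical 4-session protocol — rater 1 day 1 (A1),
#' rater 2 day 1 (B), rater 1 day 2 (A2), laboratory force platform day 3
#' (A3) — with 20 subjects, four stance tasks (two-leg 30 s, one-leg 10 s)
#' and three trials.
#'
#' Path-length trial values follow the variance-components model
#' \deqn{y_{ijk} = \mu_i + r_j + e_{ijk}}
#' with subject true scores \eqn{\mu_i \sim N(\mu_{task}, \sigma_s^2)},
#' session (rater/day) effects \eqn{r_j \sim N(0, \sigma_r^2)} drawn per
#' (task, session), and trial error \eqn{e_{ijk} \sim N(0, \sigma_e^2)}.
#' Platform sessions instead apply a fixed affine device response
#' \eqn{y = b + s\,\mu_i + e}. The implied per-trial agreement ICC between
#' two board sessions is \eqn{\sigma_s^2/(\sigma_s^2+\sigma_r^2+\sigma_e^2)};
#' after averaging the `n_trials` trials, \eqn{\sigma_e^2} shrinks by
#' `n_trials`.
#'
#' Default task means (36, 40, 44, 81 cm) and sigmas (7 / 1.5 / 3 cm) put
#' simulated path lengths and ICCs in the range reported for healthy adults
#' on consumer boards (roughly 35-85 cm, ICC 0.7-0.92).
#'
#' @param n_subjects number of subjects (default 20).
#' @param tasks data frame `task,duration_s,mean_pl_cm`.
#' @param n_trials trials per condition (default 3).
#' @param sessions session labels (default A1, B, A2, A3).
#' @param platform_sessions subset of `sessions` measured by the reference
#'   platform (fixed bias+scale instead of a random session effect).
#' @param sigma_subject,sigma_session,sigma_error variance-component SDs, cm.
#' @param device_bias,device_scale platform affine response.
#' @param seed master seed for [simulate_study()].
#' @return Object of class `study_design`; `$true_icc` is the per-trial
#'   board-vs-board agreement ICC, `$true_icc_condition` the mean-of-trials
#'   version.
#' @export
study_design <- function(n_subjects = 20,
                         tasks = data.frame(
                           task = c("STOE", "STCE", "SOOE", "SOCE"),
                           duration_s = c(30, 30, 10, 10),
                           mean_pl_cm = c(36, 40, 44, 81),
                           stringsAsFactors = FALSE),
                         n_trials = 3,
                         sessions = c("A1", "B", "A2", "A3"),
                         platform_sessions = "A3",
                         sigma_subject = 7, sigma_session = 1.5,
                         sigma_error = 3,
                         device_bias = 0, device_scale = 0.9,
                         seed = NULL) {
  if (n_subjects < 1 || n_trials < 1)
    abort_sb("need at least one subject and one trial",
             "swayboard_parameter_error")
  if (any(c(sigma_subject, sigma_session, sigma_error) < 0))
    abort_sb("variance-component sigmas must be >= 0",
             "swayboard_parameter_error")
  if (!all(platform_sessions %in% sessions))
    abort_sb("platform_sessions must be a subset of sessions",
             "swayboard_design_error")
  vs <- sigma_subject^2; vr <- sigma_session^2; ve <- sigma_error^2
  structure(list(n_subjects = as.integer(n_subjects), tasks = tasks,
                 n_trials = as.integer(n_trials), sessions = sessions,
                 platform_sessions = platform_sessions,
                 sigma_subject = sigma_subject,
                 sigma_session = sigma_session, sigma_error = sigma_error,
                 device_bias = device_bias, device_scale = device_scale,
                 seed = seed,
                 true_icc = vs / (vs + vr + ve),
                 true_icc_condition = vs / (vs + vr + ve / n_trials)),
            class = "study_design")
}

#' Simulate a full reliability study
#'
#' Draws a complete trial-metrics table from a [study_design()] (see there
#' for the variance-components model). Velocity is path length divided by
#' task duration, by construction. Trial values are floored at 0; with the
#' default parameters the truncation probability is negligible (< 1e-6).
#'
#' @param design a [study_design()].
#' @param recordings_dir optional directory: if given, every trial is also
#'   materialized as a raw four-load-cell CSV via [forces_from_cop()], with
#'   the OU trajectory calibrated so the *filtered* path length equals the
#'   table value, and a `file` column is added to the returned table.
#' @param filter [filter_spec()] used for that calibration.
#' @param load_kg simulated body mass used for the corner forces.
#' @return Trial-metrics data frame
#'   (`subject,task,session,trial,pl_cm,va_cm_s`), with attribute
#'   `ground_truth` (design parameters and true ICCs).
#' @examples
#' d <- study_design(seed = 42)
#' trials <- simulate_study(d)
#' nrow(trials)  # 20 subjects x 4 tasks x 4 sessions x 3 trials = 960
#' @export
simulate_study <- function(design, recordings_dir = NULL,
                           filter = filter_spec(), load_kg = 65) {
  if (!inherits(design, "study_design"))
    abort_sb("`design` must be a study_design", "swayboard_parameter_error")
  if (!is.null(design$seed)) set.seed(design$seed)
  subjects <- sprintf("S%02d", seq_len(design$n_subjects))

  rows <- vector("list", nrow(design$tasks) * length(design$sessions))
  i <- 0L
  for (ti in seq_len(nrow(design$tasks))) {
    task <- design$tasks$task[ti]
    dur <- design$tasks$duration_s[ti]
    mu <- stats::rnorm(design$n_subjects, design$tasks$mean_pl_cm[ti],
                       design$sigma_subject)
    for (sess in design$sessions) {
      platform <- sess %in% design$platform_sessions
      r <- if (platform) 0 else stats::rnorm(1, 0, design$sigma_session)
      base <- if (platform) design$device_bias + design$device_scale * mu
              else mu + r
      e <- matrix(stats::rnorm(design$n_subjects * design$n_trials,
                               0, design$sigma_error),
                  design$n_subjects, design$n_trials)
      y <- pmax(base + e, 0)
      i <- i + 1L
      rows[[i]] <- data.frame(
        subject = rep(subjects, times = design$n_trials),
        task = task, session = sess,
        trial = rep(seq_len(design$n_trials), each = design$n_subjects),
        pl_cm = as.vector(y), va_cm_s = as.vector(y) / dur,
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL

  if (!is.null(recordings_dir)) {
    dir.create(recordings_dir, showWarnings = FALSE, recursive = TRUE)
    trials$file <- NA_character_
    durations <- stats::setNames(design$tasks$duration_s, design$tasks$task)
    for (j in seq_len(nrow(trials))) {
      traj <- calibrated_trajectory(trials$pl_cm[j],
                                    duration_s = durations[[trials$task[j]]],
                                    filter = filter,
                                    meta = as.list(trials[j, c("subject", "task",
                                                               "session", "trial")]))
      rec <- forces_from_cop(traj, load_series = load_kg)
      f <- file.path(recordings_dir,
                     sprintf("%s_%s_%s_t%d.csv", trials$subject[j],
                             trials$task[j], trials$session[j],
                             trials$trial[j]))
      write_raw_recording(rec, f)
      trials$file[j] <- f
    }
  }

  attr(trials, "ground_truth") <- list(
    true_icc = design$true_icc,
    true_icc_condition = design$true_icc_condition,
    sigma_subject = design$sigma_subject,
    sigma_session = design$sigma_session,
    sigma_error = design$sigma_error,
    device_bias = design$device_bias, device_scale = design$device_scale,
    seed = design$seed)
  trials
}

# OU trajectory rescaled so that the low-pass-filtered path length equals
# `target`. The filter is linear with unit DC gain, so scaling about the mean
# commutes with it exactly and the calibration is exact, not approximate.
calibrated_trajectory <- function(target_pl, duration_s, filter = filter_spec(),
                                  meta = list()) {
  p <- sway_params(duration_s = duration_s, fs_hz = filter$fs_hz)
  traj <- simulate_cop_trajectory(p, meta = meta)
  pl_f <- path_length(lowpass_filter(traj, filter))
  s <- target_pl / pl_f
  traj$x <- mean(traj$x) + s * (traj$x - mean(traj$x))
  traj$y <- mean(traj$y) + s * (traj$y - mean(traj$y))
  traj
}
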