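#' COP path length
#'
#' Total distance travelled by the center of pressure over a trial:
#' \deqn{PL = \sum_{i=1}^{N-1} \sqrt{(x_{i+1}-x_i)^2 + (y_{i+1}-y_i)^2}}
#' in cm. Expects a filtered, uniformly sampled trajectory.
#'
#' @param traj a [cop_trajectory()] with >= 2 samples.
#' @return Path length, cm.
#' @export
path_length <- function(traj) {
  if (!inherits(traj, "cop_trajectory"))
    abort_sb("`traj` must be a cop_trajectory", "swayboard_format_error")
  if (length(traj$x) < 2L)
    abort_sb("need at least 2 samples for a path length",
             "swayboard_short_error")
  sum(sqrt(diff(traj$x)^2 + diff(traj$y)^2))
}

#' Average COP velocity
#'
#' Path length divided by the elapsed recorded duration T = (N-1)/fs, cm/s.
#' This is the clean kinematic definition: `mean_velocity(traj) * T` is
#' identically [path_length()].
#'
#' @inheritParams path_length
#' @return Average velocity, cm/s.
#' @export
mean_velocity <- function(traj) {
  pl <- path_length(traj)
  pl / ((length(traj$x) - 1) / traj$fs)
}

#' Per-trial sway metrics
#'
#' Runs [path_length()] and [mean_velocity()] on one trajectory and returns a
#' one-row data frame in the trial-metrics table contract
#' (`subject,task,session,trial,pl_cm,va_cm_s`).
#'
#' @param traj a preprocessed [cop_trajectory()].
#' @param meta named list with subject/task/session/trial; defaults to the
#'   trajectory's own metadata.
#' @return A one-row data frame.
#' @export
trial_metrics <- function(traj, meta = NULL) {
  meta <- meta %||% traj$meta
  data.frame(subject = as.character(meta$subject %||% NA),
             task    = as.character(meta$task %||% NA),
             session = as.character(meta$session %||% NA),
             trial   = as.integer(meta$trial %||% NA),
             pl_cm   = path_length(traj),
             va_cm_s = mean_velocity(traj),
             stringsAsFactors = FALSE)
}

#' Mean-of-trials condition summary
#'
#' Averages the repeated trials of one (subject, task, session) condition —
#' the protocol value carried into the reliability analysis is the mean of
#' the three repetitions.
#'
#' @param trials data frame of trial metrics sharing one
#'   subject/task/session key (columns `subject,task,session,pl_cm,va_cm_s`).
#' @return One-row data frame with mean `pl_cm`, `va_cm_s` and
#'   `n_trials_used`.
#' @export
summarize_condition <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    abort_sb("no trials to summarize", "swayboard_empty_error")
  key <- unique(trials[, c("subject", "task", "session")])
  if (nrow(key) != 1L)
    abort_sb("trials mix more than one subject/task/session key",
             "swayboard_grouping_error")
  data.frame(key,
             pl_cm = mean(trials$pl_cm),
             va_cm_s = mean(trials$va_cm_s),
             n_trials_used = nrow(trials),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a full trial table into condition means
#'
#' Applies [summarize_condition()] to every (subject, task, session) group of
#' a trial-metrics table.
#'
#' @param trials trial-metrics data frame
#'   (`subject,task,session,trial,pl_cm,va_cm_s`).
#' @return Condition-summary data frame, one row per group, with
#'   `n_trials_used`.
#' @export
summarize_trials <- function(trials) {
  if (!is.data.frame(trials) || nrow(trials) == 0L)
    abort_sb("empty trial table", "swayboard_empty_error")
  means <- stats::aggregate(cbind(pl_cm, va_cm_s) ~ subject + task + session,
                            data = trials, FUN = mean)
  counts <- stats::aggregate(list(n_trials_used = trials$pl_cm),
                             by = trials[c("subject", "task", "session")],
                             FUN = length)
  out <- merge(means, counts, by = c("subject", "task", "session"))
  out <- out[order(out$task, out$session, out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}
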