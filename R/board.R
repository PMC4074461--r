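#' Board geometry
#'
#' Physical layout of a four-load-cell balance board. The coordinate frame has
#' its origin at the board center; the x axis is medio-lateral (positive
#' right) spanning `width_x`, the y axis antero-posterior (positive forward,
#' i.e. towards the top/toe edge) spanning `depth_y`. The default dimensions,
#' 45 x 26.5 cm, are those of the consumer four-load-cell board used in
#' clinical balance testing.
#'
#' The anatomical-axis mapping (long axis = medio-lateral) and the raw force
#' unit (unit-agnostic: N or kg-equivalent; center of pressure is invariant to
#' uniform force scaling) are package conventions, documented here because
#' board firmware does not fix them.
#'
#' @param width_x board length along the medio-lateral axis, cm.
#' @param depth_y board length along the antero-posterior axis, cm.
#' @return An object of class `board_geometry`.
#' @examples
#' board_geometry()          # 45 x 26.5 cm default
#' board_geometry(50, 50)    # laboratory force platform footprint
#' @export
board_geometry <- function(width_x = 45, depth_y = 26.5) {
  stopifnot_number(width_x, "width_x", positive = TRUE)
  stopifnot_number(depth_y, "depth_y", positive = TRUE)
  structure(list(width_x = width_x, depth_y = depth_y),
            class = "board_geometry")
}

#' @export
print.board_geometry <- function(x, ...) {
  cat(sprintf("Board geometry: %.1f cm (ML, x) x %.1f cm (AP, y), origin at center\n",
              x$width_x, x$depth_y))
  invisible(x)
}

#' Raw four-load-cell recording
#'
#' One trial's worth of corner load-cell readings. Corner names follow the
#' board seen from above with the toe edge up: `f_tl` top-left, `f_tr`
#' top-right, `f_bl` bottom-left, `f_br` bottom-right. All four series share
#' one (arbitrary) force unit and must be non-negative; timestamps must be
#' strictly increasing.
#'
#' @param t sample times, s.
#' @param f_tl,f_tr,f_bl,f_br corner vertical force series.
#' @param geometry a [board_geometry()].
#' @param meta named list of identifiers (subject, task, session, trial).
#' @return An object of class `raw_recording` with a `samples` data frame.
#' @export
raw_recording <- function(t, f_tl, f_tr, f_bl, f_br,
                          geometry = board_geometry(), meta = list()) {
  n <- length(t)
  if (n < 2L)
    abort_sb("a recording needs at least 2 samples", "swayboard_format_error")
  lens <- c(length(f_tl), length(f_tr), length(f_bl), length(f_br))
  if (any(lens != n))
    abort_sb("force series must all have the same length as `t`",
             "swayboard_format_error")
  if (!all(is.finite(t)))
    abort_sb("timestamps must be finite", "swayboard_format_error")
  if (any(diff(t) <= 0))
    abort_sb(sprintf("timestamps must be strictly increasing (first violation at sample %d)",
                     which(diff(t) <= 0)[1] + 1L),
             "swayboard_format_error")
  f <- cbind(f_tl, f_tr, f_bl, f_br)
  if (any(!is.finite(f)) || any(f < 0))
    abort_sb("corner forces must be finite and non-negative",
             "swayboard_format_error")
  structure(list(samples = data.frame(t = t, f_tl = f_tl, f_tr = f_tr,
                                      f_bl = f_bl, f_br = f_br),
                 geometry = geometry, meta = meta),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("Raw board recording: %d samples, %.2f s\n",
              n, x$samples$t[n] - x$samples$t[1]))
  if (length(x$meta)) cat("  meta:", paste(names(x$meta), unlist(x$meta),
                                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' COP trajectory
#'
#' A (nominally uniformly sampled) 2-D center-of-pressure path. `x` is
#' medio-lateral, `y` antero-posterior, both in cm in the board frame of
#' [board_geometry()].
#'
#' @param x,y coordinate series, cm.
#' @param fs sampling rate, Hz.
#' @param t optional sample times, s (kept for resampling of jittery grids).
#' @param total_load optional per-sample summed load, input force units.
#' @param geometry optional [board_geometry()].
#' @param meta named list of identifiers.
#' @return An object of class `cop_trajectory`.
#' @export
cop_trajectory <- function(x, y, fs, t = NULL, total_load = NULL,
                           geometry = NULL, meta = list()) {
  stopifnot_number(fs, "fs", positive = TRUE)
  n <- length(x)
  if (length(y) != n)
    abort_sb("x and y must have equal length", "swayboard_format_error")
  if (!is.null(total_load) && length(total_load) != n)
    abort_sb("total_load must match the coordinate length",
             "swayboard_format_error")
  if (!is.null(t) && length(t) != n)
    abort_sb("t must match the coordinate length", "swayboard_format_error")
  structure(list(x = as.numeric(x), y = as.numeric(y), fs = fs,
                 t = if (!is.null(t)) as.numeric(t),
                 total_load = if (!is.null(total_load)) as.numeric(total_load),
                 geometry = geometry, meta = meta),
            class = "cop_trajectory")
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("COP trajectory: %d samples @ %g Hz (%.2f s)\n",
              length(x$x), x$fs, (length(x$x) - 1) / x$fs))
  cat(sprintf("  x (ML): [%.3f, %.3f] cm   y (AP): [%.3f, %.3f] cm\n",
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
length.cop_trajectory <- function(x) length(x$x)

#' Reconstruct the COP series from corner forces
#'
#' Moment balance over the four corners: with total load
#' \eqn{F = f_{tl}+f_{tr}+f_{bl}+f_{br}},
#' \deqn{x = \frac{W}{2}\,\frac{(f_{tr}+f_{br}) - (f_{tl}+f_{bl})}{F},\qquad
#'       y = \frac{D}{2}\,\frac{(f_{tl}+f_{tr}) - (f_{bl}+f_{br})}{F}}
#' where W and D are the board width (ML) and depth (AP). The reconstruction
#' is invariant to uniform scaling of the forces, so the raw unit does not
#' matter.
#'
#' Samples whose total load falls below `min_load_fraction` of the trial
#' median are unreliable (division by a near-zero load during step-on /
#' step-off) and are linearly interpolated from valid neighbours; leading and
#' trailing invalid runs are dropped.
#'
#' @param rec a [raw_recording()].
#' @param min_load_fraction invalidity threshold as a fraction of the median
#'   total load (default 0.05).
#' @return A [cop_trajectory()] whose `fs` is the recording's nominal rate
#'   \eqn{(N-1)/(t_N - t_1)}; attribute `n_interpolated` counts repaired
#'   samples.
#' @examples
#' rec <- raw_recording(t = 0:3 / 50, f_tl = rep(10, 4), f_tr = rep(30, 4),
#'                      f_bl = rep(10, 4), f_br = rep(30, 4))
#' traj <- compute_cop_series(rec)
#' head(traj$x)  # 11.25 cm: all weight shifted right
#' @export
compute_cop_series <- function(rec, min_load_fraction = 0.05) {
  if (!inherits(rec, "raw_recording"))
    abort_sb("`rec` must be a raw_recording", "swayboard_format_error")
  if (min_load_fraction <= 0 || min_load_fraction >= 1)
    abort_sb("`min_load_fraction` must be in (0, 1)",
             "swayboard_parameter_error")
  s <- rec$samples
  F <- s$f_tl + s$f_tr + s$f_bl + s$f_br
  thr <- min_load_fraction * stats::median(F)
  valid <- F >= thr & F > 0
  if (!any(valid))
    abort_sb("no sample carries enough load to locate the COP (all below threshold)",
             "swayboard_signal_error")

  # drop leading/trailing invalid runs, interpolate interior gaps
  keep <- seq(which(valid)[1], max(which(valid)))
  s <- s[keep, , drop = FALSE]
  F <- F[keep]
  valid <- valid[keep]

  g <- rec$geometry
  x <- y <- rep(NA_real_, nrow(s))
  x[valid] <- (g$width_x / 2) *
    ((s$f_tr[valid] + s$f_br[valid]) - (s$f_tl[valid] + s$f_bl[valid])) / F[valid]
  y[valid] <- (g$depth_y / 2) *
    ((s$f_tl[valid] + s$f_tr[valid]) - (s$f_bl[valid] + s$f_br[valid])) / F[valid]
  if (any(!valid)) {
    x[!valid] <- stats::approx(s$t[valid], x[valid], xout = s$t[!valid])$y
    y[!valid] <- stats::approx(s$t[valid], y[valid], xout = s$t[!valid])$y
  }

  n <- nrow(s)
  fs <- (n - 1) / (s$t[n] - s$t[1])
  out <- cop_trajectory(x, y, fs = fs, t = s$t, total_load = F,
                        geometry = g, meta = rec$meta)
  attr(out, "n_interpolated") <- sum(!valid)
  out
}

#' Decompose a COP trajectory into corner forces
#'
#' Inverse of [compute_cop_series()]: distributes the total load over the four
#' corners with bilinear weights, the unique corner decomposition that is
#' linear in (x, y) and exactly reproduces the COP under the moment-balance
#' reconstruction. Used by the simulator to materialize raw recordings.
#'
#' @param traj a [cop_trajectory()]; every point must lie inside the board
#'   rectangle.
#' @param load_series per-sample total load (> 0); defaults to the
#'   trajectory's `total_load`.
#' @param geometry a [board_geometry()]; defaults to the trajectory's.
#' @return A [raw_recording()] such that `compute_cop_series()` round-trips
#'   the input trajectory to numerical precision.
#' @export
forces_from_cop <- function(traj, load_series = NULL, geometry = NULL) {
  if (!inherits(traj, "cop_trajectory"))
    abort_sb("`traj` must be a cop_trajectory", "swayboard_format_error")
  g <- geometry %||% traj$geometry %||% board_geometry()
  load <- load_series %||% traj$total_load
  if (is.null(load))
    abort_sb("no load series: supply `load_series` or a trajectory with total_load",
             "swayboard_parameter_error")
  n <- length(traj$x)
  if (length(load) == 1L) load <- rep(load, n)
  if (any(load <= 0))
    abort_sb("load_series must be strictly positive", "swayboard_parameter_error")

  u <- traj$x / (g$width_x / 2)   # [-1, 1] left -> right
  v <- traj$y / (g$depth_y / 2)   # [-1, 1] bottom -> top
  tol <- 1e-9
  if (any(abs(u) > 1 + tol) || any(abs(v) > 1 + tol))
    abort_sb("COP lies outside the board rectangle; cannot decompose into non-negative corner forces",
             "swayboard_domain_error")
  u <- pmin(pmax(u, -1), 1); v <- pmin(pmax(v, -1), 1)

  t <- traj$t %||% ((seq_len(n) - 1) / traj$fs)
  raw_recording(t = t,
                f_tl = load * (1 - u) * (1 + v) / 4,
                f_tr = load * (1 + u) * (1 + v) / 4,
                f_bl = load * (1 - u) * (1 - v) / 4,
                f_br = load * (1 + u) * (1 - v) / 4,
                geometry = g, meta = traj$meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
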