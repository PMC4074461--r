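#' Low-pass filter specification
#'
#' Butterworth low-pass design used on the COP coordinates. Defaults mirror
#' the conventional board pipeline: 4th order, 12 Hz cut-off, 50 Hz sampling.
#' `mode = "zero_phase"` (default) applies the design forward and backward,
#' which doubles the attenuation (amplitude 1/2 at the cut-off instead of
#' 1/sqrt(2)) but leaves no phase lag — the usual choice in posturography.
#' `mode = "causal"` is the literal single forward pass.
#'
#' @param order filter order (>= 1).
#' @param cutoff_hz cut-off frequency, Hz; must be below Nyquist.
#' @param fs_hz sampling rate, Hz.
#' @param mode `"zero_phase"` or `"causal"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, cutoff_hz = 12, fs_hz = 50,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  stopifnot_number(fs_hz, "fs_hz", positive = TRUE)
  stopifnot_number(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (!is.numeric(order) || length(order) != 1L || order < 1 ||
      order != round(order))
    abort_sb("`order` must be a positive integer", "swayboard_parameter_error")
  if (cutoff_hz >= fs_hz / 2)
    abort_sb("cut-off must be below the Nyquist frequency fs/2",
             "swayboard_parameter_error")
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 fs_hz = fs_hz, mode = mode),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Butterworth low-pass: order %d, cut-off %g Hz @ %g Hz, %s\n",
              x$order, x$cutoff_hz, x$fs_hz, x$mode))
  invisible(x)
}

#' Resample a trajectory onto a uniform grid
#'
#' Linear interpolation of x, y (and total load) onto a uniform grid at
#' `target_fs` spanning the original time range. Board timestamps arrive with
#' transmission jitter; filtering assumes uniform sampling, so resampling
#' always precedes [lowpass_filter()].
#'
#' @param traj a [cop_trajectory()] with at least 2 samples.
#' @param target_fs target sampling rate, Hz.
#' @return A uniformly sampled [cop_trajectory()] with `fs = target_fs`.
#' @export
resample_uniform <- function(traj, target_fs) {
  if (!inherits(traj, "cop_trajectory"))
    abort_sb("`traj` must be a cop_trajectory", "swayboard_format_error")
  stopifnot_number(target_fs, "target_fs", positive = TRUE)
  n <- length(traj$x)
  if (n < 2L)
    abort_sb("need at least 2 samples to resample", "swayboard_short_error")
  t <- traj$t %||% ((seq_len(n) - 1) / traj$fs)
  if (anyDuplicated(t))
    abort_sb(sprintf("duplicate timestamp at sample %d", anyDuplicated(t)),
             "swayboard_format_error")
  m <- floor((t[n] - t[1]) * target_fs + 1e-9) + 1L
  grid <- t[1] + (seq_len(m) - 1L) / target_fs
  interp <- function(v) stats::approx(t, v, xout = grid, rule = 2)$y
  cop_trajectory(interp(traj$x), interp(traj$y), fs = target_fs, t = grid,
                 total_load = if (!is.null(traj$total_load)) interp(traj$total_load),
                 geometry = traj$geometry, meta = traj$meta)
}

# Forward-backward IIR pass with odd-reflection padding (3 x order samples on
# each side) and first-sample offset removal, so a constant signal passes
# through bit-exactly and startup transients on short trials stay outside the
# retained segment.
filtfilt_refl <- function(b, a, x, npad) {
  n <- length(x)
  x0 <- x[1]
  z <- x - x0
  zz <- c(2 * z[1] - z[(npad + 1):2], z, 2 * z[n] - z[(n - 1):(n - npad)])
  y <- as.numeric(signal::filter(b, a, zz))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(npad + 1):(npad + n)] + x0
}

#' Low-pass filter a COP trajectory
#'
#' Applies the Butterworth design of a [filter_spec()] to the x and y
#' coordinate series. The trajectory must be uniformly sampled at the spec's
#' rate (use [resample_uniform()] first).
#'
#' In `zero_phase` mode the signal is padded on each side with 3 x order
#' samples by odd reflection about the endpoints, filtered forward and
#' backward, and trimmed; this suppresses startup transients that would
#' otherwise bite into 10 s one-leg trials. In `causal` mode a single forward
#' pass is applied with steady-state initialization at the first sample
#' (the filter state is primed as if the signal had been at its first value
#' forever).
#'
#' @param traj a uniformly sampled [cop_trajectory()].
#' @param spec a [filter_spec()].
#' @return The filtered [cop_trajectory()].
#' @examples
#' traj <- cop_trajectory(x = rep(3, 100), y = rep(0, 100), fs = 50)
#' filt <- lowpass_filter(traj, filter_spec())
#' all.equal(filt$x, rep(3, 100))  # unit DC gain
#' @export
lowpass_filter <- function(traj, spec = filter_spec()) {
  if (!inherits(traj, "cop_trajectory"))
    abort_sb("`traj` must be a cop_trajectory", "swayboard_format_error")
  if (!inherits(spec, "filter_spec"))
    abort_sb("`spec` must be a filter_spec", "swayboard_parameter_error")
  if (abs(traj$fs - spec$fs_hz) > 1e-6 * spec$fs_hz)
    abort_sb(sprintf("trajectory sampled at %g Hz but filter designed for %g Hz; resample first",
                     traj$fs, spec$fs_hz),
             "swayboard_parameter_error")
  n <- length(traj$x)
  npad <- 3L * spec$order
  if (n <= npad)
    abort_sb(sprintf("trajectory too short to filter: %d samples <= warm-up of %d",
                     n, npad),
             "swayboard_short_error")
  bf <- signal::butter(spec$order, 2 * spec$cutoff_hz / spec$fs_hz,
                       type = "low")
  apply1 <- function(v) {
    if (spec$mode == "zero_phase") {
      filtfilt_refl(bf$b, bf$a, v, npad)
    } else {
      v0 <- v[1]
      as.numeric(signal::filter(bf$b, bf$a, v - v0)) + v0
    }
  }
  out <- traj
  out$x <- apply1(traj$x)
  out$y <- apply1(traj$y)
  out
}
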