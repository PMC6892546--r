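#' Uniform time grid
#'
#' All signals in the package live on a uniform, stimulus-locked time grid.
#' `t0` is the time of the first sample relative to stimulus onset (negative
#' for pre-stimulus baseline samples).
#'
#' @param dt Sample interval in seconds (> 0). The default 0.001 s corresponds
#'   to field-potential recordings downsampled to 1000 Hz.
#' @param n Number of samples (>= 2).
#' @param t0 Time of the first sample in seconds (default 0, stimulus onset).
#' @return An object of class `time_grid` with fields `dt`, `n`, `t0`.
#' @export
time_grid <- function(dt = 0.001, n, t0 = 0) {
  stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(n), length(n) == 1L, n >= 2,
            is.numeric(t0), length(t0) == 1L)
  structure(list(dt = dt, n = as.integer(n), t0 = t0), class = "time_grid")
}

#' Time axis of a grid
#'
#' @param grid A `time_grid`.
#' @return Numeric vector of sample times in seconds.
#' @export
grid_times <- function(grid) {
  stopifnot(inherits(grid, "time_grid"))
  grid$t0 + (seq_len(grid$n) - 1) * grid$dt
}

same_dt <- function(a, b) {
  abs(a$dt - b$dt) <= 1e-12 * max(a$dt, b$dt)
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("<time_grid> dt = %g s, n = %d, t = [%g, %g] s\n",
              x$dt, x$n, x$t0, x$t0 + (x$n - 1) * x$dt))
  invisible(x)
}

#' Stimulus contrast time course
#'
#' The model input: one contrast value in [0, 1] per sample (0 = blank
#' screen, 1 = full contrast).
#'
#' @param values Numeric vector of per-sample contrast values in [0, 1].
#' @param grid A `time_grid` with `n == length(values)`.
#' @return An object of class `stimulus_timecourse`.
#' @export
stimulus_timecourse <- function(values, grid) {
  stopifnot(inherits(grid, "time_grid"), length(values) == grid$n)
  if (any(!is.finite(values)) || any(values < 0 | values > 1)) {
    stop("stimulus contrast values must be finite and within [0, 1]")
  }
  structure(list(values = as.numeric(values), grid = grid),
            class = "stimulus_timecourse")
}

#' Step (sustained) stimulus
#'
#' Builds a contrast step: blank until `onset`, contrast `contrast` for
#' `duration` seconds, blank until `total` seconds.
#'
#' @param duration Stimulus-on duration in seconds.
#' @param total Total length of the time course in seconds.
#' @param contrast Contrast level in [0, 1] (default 1).
#' @param onset Time of stimulus onset in seconds relative to `t0` = 0
#'   (default 0).
#' @param dt Sample interval in seconds.
#' @param t0 Time of the first sample (default 0; use -0.2 for an epoch with
#'   a 200 ms pre-stimulus baseline).
#' @return A `stimulus_timecourse`.
#' @export
stim_step <- function(duration, total, contrast = 1, onset = 0,
                      dt = 0.001, t0 = 0) {
  grid <- time_grid(dt = dt, n = round(total / dt), t0 = t0)
  v <- numeric(grid$n)
  v[pulse_idx(onset, duration, grid)] <- contrast
  stimulus_timecourse(v, grid)
}

# Sample indices of a pulse [onset, onset + duration); computed from
# rounded sample counts so pulse lengths are exact regardless of float
# representation of the times.
pulse_idx <- function(onset, duration, grid) {
  i0 <- round((onset - grid$t0) / grid$dt)
  len <- round(duration / grid$dt)
  idx <- seq_len(len) + i0
  idx[idx >= 1 & idx <= grid$n]
}

#' Two-pulse stimulus
#'
#' Two pulses of equal duration and contrast separated by an inter-stimulus
#' interval (ISI).
#'
#' @param pulse Duration of each pulse in seconds.
#' @param isi Inter-stimulus interval (offset of first pulse to onset of
#'   second) in seconds.
#' @inheritParams stim_step
#' @return A `stimulus_timecourse`.
#' @export
stim_two_pulse <- function(pulse, isi, total, contrast = 1, onset = 0,
                           dt = 0.001, t0 = 0) {
  grid <- time_grid(dt = dt, n = round(total / dt), t0 = t0)
  v <- numeric(grid$n)
  v[pulse_idx(onset, pulse, grid)] <- contrast
  v[pulse_idx(onset + pulse + isi, pulse, grid)] <- contrast
  stimulus_timecourse(v, grid)
}

#' Model or measured response time course
#'
#' @param values Numeric vector, one response value per sample.
#' @param grid A `time_grid` with `n == length(values)`.
#' @param stage One of `"linear"`, `"rectified_exponentiated"`,
#'   `"normalized"`, `"measured"`. Normalized-stage responses must be
#'   nonnegative.
#' @return An object of class `response_timecourse`.
#' @export
response_timecourse <- function(values, grid,
                                stage = c("measured", "linear",
                                          "rectified_exponentiated",
                                          "normalized")) {
  stage <- match.arg(stage)
  stopifnot(inherits(grid, "time_grid"), length(values) == grid$n)
  if (stage == "normalized" && any(values < -1e-12)) {
    stop("normalized-stage responses must be nonnegative")
  }
  structure(list(values = as.numeric(values), grid = grid, stage = stage),
            class = "response_timecourse")
}

#' @export
print.response_timecourse <- function(x, ...) {
  cat(sprintf("<response_timecourse> stage = %s, n = %d, peak = %.4g\n",
              x$stage, x$grid$n, max(x$values)))
  invisible(x)
}

#' @export
print.stimulus_timecourse <- function(x, ...) {
  on <- sum(x$values > 0) * x$grid$dt
  cat(sprintf("<stimulus_timecourse> n = %d, nonzero for %.3g s, max contrast %.3g\n",
              x$grid$n, on, max(x$values)))
  invisible(x)
}

# Accept either a response/stimulus object or a bare numeric vector.
as_values <- function(x) {
  if (inherits(x, c("response_timecourse", "stimulus_timecourse"))) x$values
  else as.numeric(x)
}
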