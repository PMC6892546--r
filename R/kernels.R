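#' Temporal impulse response kernels
#'
#' The linear stage of the model uses a gamma-function impulse response
#' h(t) = t * exp(-t / tau1) (a shape-2 gamma, peaking at t = tau1),
#' optionally made biphasic by subtracting a weighted, slower copy whose
#' peak falls at 1.5 * tau1. The normalization pool uses an exponential
#' low-pass h2(t) = exp(-t / tau2). Monophasic and low-pass kernels are
#' normalized to unit sum so that convolution preserves the level of a
#' sustained input; the biphasic kernel consequently sums to 1 - w.
#'
#' @name kernels
NULL

# Default kernel support, starting at t = 0. The shape-2 gamma needs about
# 6.7 * tau to capture 99% of its mass (the exponential only 4.6 * tau), so
# the default span is mult * tau with a 1.2 s floor.
kernel_grid <- function(tau, dt = 0.001, mult = 8) {
  span <- max(mult * tau, 1.2)
  time_grid(dt = dt, n = max(2L, ceiling(span / dt) + 1L), t0 = 0)
}

new_kernel <- function(values, grid, kind) {
  structure(list(values = values, grid = grid, kind = kind), class = "kernel")
}

#' @export
print.kernel <- function(x, ...) {
  cat(sprintf("<kernel> kind = %s, n = %d, sum = %.6g\n",
              x$kind, x$grid$n, sum(x$values)))
  invisible(x)
}

#' Unit-sum gamma impulse response
#'
#' `h(t) = t * exp(-t / tau1)` sampled on `grid` and divided by its sum, so
#' the kernel has unit gain. The raw function peaks at `t = tau1`.
#'
#' @param tau1 Peak time in seconds (> 0).
#' @param grid A `time_grid` starting at 0; it must capture at least 99% of
#'   the kernel mass (about 6.7 * tau1), otherwise a support error is
#'   raised. Defaults to `max(8 * tau1, 1.2)` seconds at `dt`.
#' @param dt Sample interval used for the default grid.
#' @return A `kernel` of kind `"gamma"`.
#' @export
make_gamma_kernel <- function(tau1, grid = kernel_grid(tau1, dt), dt = 0.001) {
  stopifnot(tau1 > 0, inherits(grid, "time_grid"))
  t <- grid_times(grid)
  raw <- t * exp(-t / tau1)
  raw[t < 0] <- 0
  # fraction of the analytic integral tau1^2 captured on [0, T]
  T <- max(t)
  frac <- 1 - exp(-T / tau1) * (1 + T / tau1)
  if (frac < 0.99) {
    stop("kernel support error: grid spans less than 99% of the gamma kernel mass; ",
         "extend the grid to at least about 7 * tau1")
  }
  new_kernel(raw / sum(raw), grid, "gamma")
}

#' Biphasic impulse response
#'
#' Weighted difference of two unit-sum gamma kernels,
#' `h1 = g(tau1) - w * g(1.5 * tau1)`: the negative lobe peaks at exactly
#' 1.5 * tau1 and the kernel sums to `1 - w`. `w = 0` gives the monophasic
#' kernel; `w = 1` is maximally biphasic (zero net gain, so a sustained
#' stimulus produces no sustained linear response).
#'
#' @param tau1 Peak time of the positive lobe, seconds.
#' @param w Weight of the negative lobe, in [0, 1].
#' @param grid Optional `time_grid`; defaults to a span of
#'   `max(8 * 1.5 * tau1, 1.2)` seconds (covering the slower lobe).
#' @param dt Sample interval used for the default grid.
#' @return A `kernel` of kind `"biphasic"`.
#' @export
make_biphasic_irf <- function(tau1, w, grid = kernel_grid(1.5 * tau1, dt),
                              dt = 0.001) {
  if (!is.numeric(w) || length(w) != 1L || w < 0 || w > 1) {
    stop("w must lie in [0, 1]")
  }
  g1 <- make_gamma_kernel(tau1, grid)
  g2 <- make_gamma_kernel(1.5 * tau1, grid)
  new_kernel(g1$values - w * g2$values, grid, "biphasic")
}

#' Exponential low-pass kernel for the normalization pool
#'
#' `h2(t) = exp(-t / tau2)`, normalized to unit sum so that the pool signal
#' is a weighted average of the response history (this makes the
#' semi-saturation constant commensurate with contrast units and gives the
#' steady state a closed form).
#'
#' @param tau2 Decay time constant in seconds (> 0).
#' @param grid Optional `time_grid` (must span >= 5 * tau2).
#' @param dt Sample interval used for the default grid.
#' @return A `kernel` of kind `"exp_lowpass"`.
#' @export
make_exponential_lowpass <- function(tau2, grid = kernel_grid(tau2, dt,
                                                              mult = 5),
                                     dt = 0.001) {
  stopifnot(tau2 > 0, inherits(grid, "time_grid"))
  t <- grid_times(grid)
  raw <- exp(-t / tau2)
  raw[t < 0] <- 0
  T <- max(t)
  if (1 - exp(-T / tau2) < 0.99) {
    stop("kernel support error: grid spans less than 99% of the low-pass kernel mass; ",
         "extend the grid to at least 5 * tau2")
  }
  new_kernel(raw / sum(raw), grid, "exp_lowpass")
}

# Causal discrete convolution of a signal with a kernel, truncated to the
# signal length. Kernels are unit-sum (not unit-integral), so the result of
# filtering a sustained unit input asymptotes at the kernel sum. Kernel
# samples beyond the signal length cannot reach the truncated output and
# are dropped; padding to a power of two keeps the FFT off slow lengths.
convolve_causal <- function(x, kernel_values) {
  n <- length(x)
  h <- kernel_values[seq_len(min(length(kernel_values), n))]
  L <- stats::nextn(n + length(h) - 1, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(L - n))) *
                       stats::fft(c(h, numeric(L - length(h)))),
                     inverse = TRUE)) / L
  y[seq_len(n)]
}

#' Linear stage: convolve a stimulus with an impulse response
#'
#' @param stim A `stimulus_timecourse`.
#' @param irf A `kernel` sharing the stimulus sample interval.
#' @return A `response_timecourse` with stage `"linear"`.
#' @export
linear_response <- function(stim, irf) {
  stopifnot(inherits(stim, "stimulus_timecourse"), inherits(irf, "kernel"))
  if (!same_dt(stim$grid, irf$grid)) {
    stop("grid error: stimulus and kernel sample intervals differ")
  }
  response_timecourse(convolve_causal(stim$values, irf$values), stim$grid,
                      stage = "linear")
}
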