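#' Delayed-normalization model parameters
#'
#' The model has five shape parameters and two nuisance parameters:
#' * `tau1` — peak time (s) of the first gamma lobe of the impulse response;
#'   sets the temporal summation window.
#' * `w` — weight of the negative (slower) lobe, in [0, 1]; larger values
#'   produce larger stimulus-offset transients.
#' * `tau2` — decay constant (s) of the exponential low-pass applied to the
#'   normalization pool; larger values give a smoother decay from the onset
#'   transient.
#' * `n` — expansive exponent (> 0) applied to numerator and denominator.
#' * `sigma` — semi-saturation constant (contrast units, >= 0).
#' * `shift` — nuisance onset latency (s, >= 0), implemented as a pure
#'   output delay.
#' * `gain` — nuisance output scale (> 0).
#'
#' The gamma shape parameter is fixed at m = 2 (the `t * exp(-t/tau)` form).
#'
#' @param tau1,w,tau2,n,sigma,shift,gain See above. Defaults are the
#'   standard simulation parameters `w = 0, tau1 = 0.05, tau2 = 0.1, n = 2,
#'   sigma = 1`.
#' @return An object of class `dn_params`.
#' @export
dn_params <- function(tau1 = 0.05, w = 0, tau2 = 0.1, n = 2, sigma = 1,
                      shift = 0, gain = 1) {
  stopifnot(tau1 > 0, tau2 > 0, n > 0, sigma >= 0, shift >= 0, gain > 0)
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  structure(list(tau1 = tau1, w = w, tau2 = tau2, n = n, sigma = sigma,
                 shift = shift, gain = gain, m = 2),
            class = "dn_params")
}

#' @export
print.dn_params <- function(x, ...) {
  cat(sprintf(
    "<dn_params> tau1 = %.4g s, w = %.3g, tau2 = %.4g s, n = %.3g, sigma = %.4g | shift = %.4g s, gain = %.4g\n",
    x$tau1, x$w, x$tau2, x$n, x$sigma, x$shift, x$gain))
  invisible(x)
}

# Delay a vector by shift/dt samples, zero-padding at the front. Fractional
# delays are linearly interpolated so the delay is continuous in shift
# (a quantized delay would make fitted objectives piecewise-constant in the
# latency parameter); an integer-sample shift is exact.
apply_shift <- function(values, shift, dt) {
  s <- shift / dt
  if (s <= 0) return(values)
  n <- length(values)
  k <- floor(s)
  f <- s - k
  pad_k <- c(rep(0, min(k, n)), values)[seq_len(n)]
  if (f == 0) return(pad_k)
  pad_k1 <- c(rep(0, min(k + 1, n)), values)[seq_len(n)]
  (1 - f) * pad_k + f * pad_k1
}

#' Delayed-normalization forward model
#'
#' Computes the model response to a contrast time course: the stimulus is
#' convolved with the (possibly biphasic) impulse response, full-wave
#' rectified, and divisively normalized by `sigma^n` plus the exponentiated
#' low-pass-filtered rectified drive:
#'
#' `R(t) = |R_L(t)|^n / ( sigma^n + [ (h2 * |R_L|)(t) ]^n )`
#'
#' then delayed by `shift` and scaled by `gain`.
#'
#' @param stim A `stimulus_timecourse`.
#' @param params A `dn_params` object.
#' @param denominator Which signal the pool low-pass filters. The default
#'   `"low_pass_then_power"` filters the rectified linear drive and then
#'   raises the pool to the power `n`; `"power_then_low_pass"` filters the
#'   already-exponentiated drive `|R_L|^n` instead.
#' @return A `response_timecourse` with stage `"normalized"`.
#' @export
dn_response <- function(stim, params,
                        denominator = c("low_pass_then_power",
                                        "power_then_low_pass")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(stim, "stimulus_timecourse"),
            inherits(params, "dn_params"))
  dt <- stim$grid$dt
  irf <- make_biphasic_irf(params$tau1, params$w, dt = dt)
  rl <- abs(convolve_causal(stim$values, irf$values))
  if (params$sigma == 0 && all(stim$values == 0)) {
    return(response_timecourse(numeric(stim$grid$n), stim$grid, "normalized"))
  }
  if (params$sigma == 0) {
    warning("sigma = 0: response is undefined wherever the drive is 0; ",
            "zeros are substituted at those samples")
  }
  h2 <- make_exponential_lowpass(params$tau2, dt = dt)
  num <- rl ^ params$n
  pool <- if (denominator == "low_pass_then_power") {
    pmax(convolve_causal(rl, h2$values), 0) ^ params$n
  } else {
    convolve_causal(num, h2$values)
  }
  den <- params$sigma ^ params$n + pool
  r <- ifelse(den > 0, num / den, 0)
  r <- params$gain * apply_shift(r, params$shift, dt)
  response_timecourse(pmax(r, 0), stim$grid, "normalized")
}

#' Cascaded delayed-normalization model
#'
#' Applies the model repeatedly: stage 1 takes the stimulus contrast time
#' course; each later stage takes the previous stage's output, rescaled to a
#' maximum of 1 so it is a valid contrast input. All stages share the same
#' parameters. Cascading delays the time to peak and reduces the relative
#' offset response, qualitatively mimicking responses in later visual areas.
#'
#' @inheritParams dn_response
#' @param n_stages Number of cascaded stages (>= 1). `n_stages = 1` is
#'   identical to [dn_response()].
#' @return A `response_timecourse` with stage `"normalized"`.
#' @export
cascade_dn <- function(stim, params, n_stages = 2) {
  if (!is.numeric(n_stages) || n_stages < 1) {
    stop("n_stages must be a positive integer")
  }
  n_stages <- as.integer(n_stages)
  out <- dn_response(stim, params)
  if (n_stages == 1L) return(out)
  for (k in seq_len(n_stages - 1L)) {
    mx <- max(out$values)
    if (mx == 0) return(out)  # zero propagates through every stage
    nxt <- stimulus_timecourse(out$values / mx, out$grid)
    out <- dn_response(nxt, params)
  }
  out
}

#' Summary metrics of a sustained-stimulus response
#'
#' Two interpretable summaries of the transient-then-sustained response
#' shape:
#' * `t_peak` — time from stimulus onset to the response peak, excluding the
#'   fitted onset latency (`shift`). Longer values indicate a longer
#'   temporal summation window.
#' * `r_asymp` — asymptotic response level as a fraction of the peak,
#'   computed as the mean over the final 20% of the stimulus-on window
#'   divided by the peak. Lower values indicate stronger gain control.
#'
#' @param resp A `response_timecourse` to a sustained stimulus.
#' @param shift Onset latency (s) to exclude from `t_peak` (default 0).
#' @param stim_onset,stim_offset Stimulus-on window in seconds on the
#'   response grid.
#' @return A list with `t_peak`, `r_asymp`, and `peak_amplitude`.
#' @export
summarize_dynamics <- function(resp, shift = 0, stim_onset = 0, stim_offset) {
  stopifnot(inherits(resp, "response_timecourse"), stim_offset > stim_onset)
  v <- resp$values
  if (all(v == 0)) stop("metrics undefined for an all-zero response")
  t <- grid_times(resp$grid)
  ipk <- which.max(v)
  tail_start <- stim_offset - 0.2 * (stim_offset - stim_onset)
  tail_idx <- t >= tail_start & t <= stim_offset
  if (!any(tail_idx)) stop("stimulus-on window does not overlap the response grid")
  list(t_peak = t[ipk] - shift,
       r_asymp = mean(v[tail_idx]) / v[ipk],
       peak_amplitude = v[ipk])
}

#' Peak dynamics across a contrast family
#'
#' For a set of responses to the same stimulus at different contrasts,
#' tabulates peak amplitude and peak time per contrast. Under delayed
#' normalization the peak grows and arrives earlier as contrast increases.
#'
#' @param responses List of `response_timecourse` objects (or numeric
#'   vectors) on a common grid.
#' @param contrasts Numeric vector of contrast levels, same length.
#' @param dt Sample interval, used when `responses` are bare vectors.
#' @return A data frame with columns `contrast`, `peak_time`, `peak_amp`.
#' @export
contrast_dynamics <- function(responses, contrasts, dt = 0.001) {
  stopifnot(length(responses) == length(contrasts))
  rows <- lapply(seq_along(responses), function(i) {
    v <- as_values(responses[[i]])
    tt <- if (inherits(responses[[i]], "response_timecourse")) {
      grid_times(responses[[i]]$grid)
    } else {
      (seq_along(v) - 1) * dt
    }
    ipk <- which.max(v)
    data.frame(contrast = contrasts[i], peak_time = tt[ipk], peak_amp = v[ipk])
  })
  do.call(rbind, rows)
}
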