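#' Compressive temporal summation (CTS) model parameters
#'
#' The CTS model is the instantaneous-normalization special case: the same
#' linear-rectify-exponentiate front end, but the gain pool is the momentary
#' drive itself rather than its low-passed history. It is the limit of the
#' delayed model as `tau2` shrinks to a single sample, and it cannot produce
#' a decay after the onset transient for a sustained stimulus.
#'
#' @param tau1,w,n,sigma,shift,gain As in [dn_params()]; `n` defaults to 2,
#'   the value conventionally fixed when fitting this model.
#' @return An object of class `cts_params`.
#' @export
cts_params <- function(tau1 = 0.05, w = 0, n = 2, sigma = 1,
                       shift = 0, gain = 1) {
  stopifnot(tau1 > 0, n > 0, sigma >= 0, shift >= 0, gain > 0)
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  structure(list(tau1 = tau1, w = w, n = n, sigma = sigma,
                 shift = shift, gain = gain),
            class = "cts_params")
}

#' Compressive temporal summation response
#'
#' `R(t) = R_L(t)^n / (sigma^n + R_L(t)^n)` pointwise on the rectified
#' linear response, then delayed by `shift` and scaled by `gain`. The
#' response is bounded above by `gain`.
#'
#' @param stim A `stimulus_timecourse`.
#' @param params A `cts_params` object.
#' @return A `response_timecourse` with stage `"normalized"`.
#' @export
cts_response <- function(stim, params) {
  stopifnot(inherits(stim, "stimulus_timecourse"),
            inherits(params, "cts_params"))
  dt <- stim$grid$dt
  irf <- make_biphasic_irf(params$tau1, params$w, dt = dt)
  rl <- abs(convolve_causal(stim$values, irf$values))
  if (params$sigma == 0 && all(stim$values == 0)) {
    return(response_timecourse(numeric(stim$grid$n), stim$grid, "normalized"))
  }
  num <- rl ^ params$n
  den <- params$sigma ^ params$n + num
  r <- ifelse(den > 0, num / den, 0)
  r <- params$gain * apply_shift(r, params$shift, dt)
  response_timecourse(pmax(r, 0), stim$grid, "normalized")
}

#' Two-temporal-channels model parameters
#'
#' @param a Sustained-channel weight (>= 0).
#' @param b Transient-channel weight (>= 0).
#' @param tau1 Shared impulse-response time constant (s).
#' @return An object of class `two_channel_params`.
#' @export
two_channel_params <- function(a = 1, b = 1, tau1 = 0.05) {
  if (!is.numeric(a) || !is.numeric(b) || a < 0 || b < 0) {
    stop("channel weights a and b must be nonnegative")
  }
  stopifnot(tau1 > 0)
  structure(list(a = a, b = b, tau1 = tau1), class = "two_channel_params")
}

#' Two-temporal-channels response
#'
#' A weighted sum of a sustained channel (linear convolution with a
#' monophasic gamma impulse response) and a transient channel (convolution
#' with a fully biphasic impulse response, squared pointwise):
#'
#' `R(t) = a * (IRF_s * S)(t) + b * (IRF_t * S)(t)^2`
#'
#' The sustained channel carries the stimulus level; the squared transient
#' channel produces bumps at both stimulus onset and offset. Because the
#' model lacks gain control, scaling the stimulus contrast scales the
#' response but leaves the peak time unchanged. The channel filters are
#' built from the package's own gamma family (monophasic for the sustained
#' channel, maximally biphasic for the transient channel); the historical
#' model used closely related filters.
#'
#' @param stim A `stimulus_timecourse`.
#' @param params A `two_channel_params` object.
#' @return A `response_timecourse` (stage `"measured"`-free; returned as
#'   `"normalized"` since it is nonnegative).
#' @export
two_channel_response <- function(stim, params) {
  stopifnot(inherits(stim, "stimulus_timecourse"),
            inherits(params, "two_channel_params"))
  dt <- stim$grid$dt
  irf_s <- make_gamma_kernel(params$tau1, dt = dt)
  irf_t <- make_biphasic_irf(params$tau1, w = 1, dt = dt)
  sus <- convolve_causal(stim$values, irf_s$values)
  trans <- convolve_causal(stim$values, irf_t$values)
  r <- params$a * sus + params$b * trans ^ 2
  response_timecourse(r, stim$grid, "normalized")
}
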