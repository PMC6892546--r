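#' Simulate noisy trial observations from the model
#'
#' Each trial is the noiseless model response plus iid additive Gaussian
#' noise (the estimation objective is squared error on trial averages, so
#' Gaussian noise is the matched noise model). Deterministic under
#' `rng_seed`.
#'
#' @param params A `dn_params` (its `gain` scales the signal).
#' @param stim A `stimulus_timecourse`.
#' @param n_trials Number of trials (>= 1).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param rng_seed Integer seed.
#' @return Numeric matrix, trials x time; the noiseless model time course
#'   is attached as attribute `"truth"`.
#' @export
simulate_observation <- function(params, stim, n_trials = 30,
                                 noise_sd = 0.1, rng_seed = 1) {
  stopifnot(n_trials >= 1, noise_sd >= 0)
  truth <- dn_response(stim, params)$values
  set.seed(rng_seed)
  trials <- matrix(rep(truth, each = n_trials) +
                     stats::rnorm(n_trials * length(truth), sd = noise_sd),
                   nrow = n_trials)
  attr(trials, "truth") <- truth
  trials
}

#' Simulate a contrast family of PSTH-like responses
#'
#' Responses to a brief (default 200 ms) stimulus presented at a set of
#' contrast levels (default 0 to 0.9 in ten equal steps): each condition is
#' the model response to the contrast-scaled stimulus plus additive
#' Gaussian noise.
#'
#' @param params A `dn_params`.
#' @param contrasts Contrast levels in [0, 1] (default
#'   `seq(0, 0.9, by = 0.1)`).
#' @param stim_duration Stimulus-on duration in seconds (default 0.2).
#' @param total Epoch length in seconds (default 0.8).
#' @param dt Sample interval (default 0.001 s).
#' @param noise_sd Additive noise SD (default 0).
#' @param rng_seed Integer seed.
#' @return A list with `psths` (list of numeric vectors, one per
#'   contrast), `contrasts`, `stims`, `grid`, and `truth` (noiseless
#'   responses).
#' @export
simulate_contrast_psths <- function(params, contrasts = seq(0, 0.9, by = 0.1),
                                    stim_duration = 0.2, total = 0.8,
                                    dt = 0.001, noise_sd = 0, rng_seed = 1) {
  stopifnot(all(contrasts >= 0 & contrasts <= 1))
  stims <- lapply(contrasts, function(cc) {
    stim_step(stim_duration, total, contrast = cc, dt = dt)
  })
  truth <- lapply(stims, function(s) dn_response(s, params)$values)
  set.seed(rng_seed)
  psths <- lapply(truth, function(v) v + stats::rnorm(length(v),
                                                      sd = noise_sd))
  list(psths = psths, contrasts = contrasts, stims = stims,
       grid = stims[[1]]$grid, truth = truth)
}

# 1/f ("pink") noise by spectral shaping of white Gaussian noise.
pink_noise <- function(n) {
  X <- stats::fft(stats::rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)  # two-sided frequency index
  Re(stats::fft(X / sqrt(f), inverse = TRUE) / n)
}

# Gaussian noise band-limited to [f_lo, f_hi] Hz by FFT masking.
bandlimited_noise <- function(n, fs, f_lo, f_hi) {
  X <- stats::fft(stats::rnorm(n))
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < f_lo | f > f_hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE) / n)
  y / stats::sd(y)
}

#' Simulate raw voltage epochs with a known broadband envelope
#'
#' Generates electrode x trial x time voltage as the sum of a 1/f (pink)
#' background, band-limited (default 70-210 Hz) Gaussian noise whose
#' amplitude follows the supplied envelope, and sinusoidal line-noise
#' components at the line frequency and its harmonics. This is the
#' ground-truth generator for the broadband-extraction chain: the
#' extracted broadband power should track the squared envelope.
#'
#' @param envelope Numeric vector (one value per sample, >= 0): the
#'   amplitude modulation of the high-frequency component.
#' @param n_electrodes,n_trials Array dimensions.
#' @param fs Sampling rate in Hz (default 1000).
#' @param band Frequency range of the modulated noise (default
#'   `c(70, 210)` Hz).
#' @param line_freq Line frequency in Hz (default 60; 0 disables).
#' @param line_amp Amplitude of each line harmonic (default 1).
#' @param pink_amp Amplitude of the pink-noise background (default 1).
#' @param t0 Epoch start in seconds (default -0.2).
#' @param rng_seed Integer seed.
#' @return A `voltage_epochs` object.
#' @export
simulate_voltage <- function(envelope, n_electrodes = 1, n_trials = 10,
                             fs = 1000, band = c(70, 210), line_freq = 60,
                             line_amp = 1, pink_amp = 1, t0 = -0.2,
                             rng_seed = 1) {
  stopifnot(all(envelope >= 0))
  n <- length(envelope)
  set.seed(rng_seed)
  tt <- (seq_len(n) - 1) / fs
  line <- 0
  if (line_freq > 0) {
    for (h in seq(line_freq, fs / 2 - line_freq, by = line_freq)) {
      line <- line + line_amp * sin(2 * pi * h * tt +
                                      stats::runif(1, 0, 2 * pi))
    }
  }
  v <- array(0, c(n_electrodes, n_trials, n))
  for (e in seq_len(n_electrodes)) {
    for (tr in seq_len(n_trials)) {
      v[e, tr, ] <- pink_amp * pink_noise(n) +
        envelope * bandlimited_noise(n, fs, band[1], band[2]) + line
    }
  }
  voltage_epochs(v, fs = fs, t0 = t0)
}

#' Demo multi-electrode dataset with graded dynamics
#'
#' Generates a small synthetic electrode set emulating the qualitative
#' organization seen across human visual cortex: 4 ROIs (V1, V2, V3,
#' anterior) x 3 eccentricity bins, with the temporal summation window
#' (hence time to peak) lengthening and gain control strengthening from V1
#' to anterior maps, and the negative-lobe weight `w` (offset-transient
#' size) growing from fovea to periphery. Each electrode's response is the
#' model output for its true parameters plus additive Gaussian noise. The
#' generating parameters ship with the dataset as the ground-truth table.
#'
#' @param rng_seed Integer seed.
#' @param noise_sd Additive noise SD on each electrode's trial-averaged
#'   time course (default 0.02).
#' @param dt Sample interval (default 0.001 s).
#' @return A list with `responses` (electrode x time matrix), `stim` (the
#'   shared 500 ms step in a 1.2 s epoch), `meta` (data frame: electrode,
#'   roi, eccentricity, true tau1/w/tau2/n/sigma/gain).
#' @export
make_demo_dataset <- function(rng_seed = 1, noise_sd = 0.02, dt = 0.001) {
  rois <- c("V1", "V2", "V3", "anterior")
  eccs <- c(3, 7, 12)  # one electrode per eccentricity bin
  # ROI gradients: longer summation (tau1) and smoother, stronger gain
  # control (larger tau2, smaller sigma) anteriorly; w grows with
  # eccentricity. The exponent stays at 2 so the per-electrode biphasic
  # fit (which fixes n = 2) is well specified. The sustained-step time to
  # peak runs from about 115 ms (V1) to about 146 ms (anterior).
  tau1_by_roi <- c(V1 = 0.14, V2 = 0.16, V3 = 0.19, anterior = 0.23)
  tau2_by_roi <- c(V1 = 0.10, V2 = 0.12, V3 = 0.14, anterior = 0.17)
  n_by_roi <- c(V1 = 2, V2 = 2, V3 = 2, anterior = 2)
  sigma_by_roi <- c(V1 = 0.050, V2 = 0.040, V3 = 0.032, anterior = 0.026)
  w_by_ecc <- c(0.45, 0.6, 0.8)
  stim <- stim_step(0.5, 1.2, dt = dt, t0 = -0.2, onset = 0)
  meta <- expand.grid(roi = rois, eccentricity = eccs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$electrode <- seq_len(nrow(meta))
  meta$tau1 <- tau1_by_roi[meta$roi]
  meta$w <- w_by_ecc[match(meta$eccentricity, eccs)]
  meta$tau2 <- tau2_by_roi[meta$roi]
  meta$n <- n_by_roi[meta$roi]
  meta$sigma <- sigma_by_roi[meta$roi]
  meta$gain <- 1
  set.seed(rng_seed)
  responses <- t(vapply(seq_len(nrow(meta)), function(i) {
    p <- dn_params(tau1 = meta$tau1[i], w = meta$w[i], tau2 = meta$tau2[i],
                   n = meta$n[i], sigma = meta$sigma[i], gain = meta$gain[i])
    dn_response(stim, p)$values + stats::rnorm(stim$grid$n, sd = noise_sd)
  }, numeric(stim$grid$n)))
  meta <- meta[, c("electrode", "roi", "eccentricity", "tau1", "w", "tau2",
                   "n", "sigma", "gain")]
  list(responses = responses, stim = stim, meta = meta)
}
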