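# Independent brute-force reference implementations used as oracles. These
# deliberately avoid the package's FFT convolution and vectorized paths:
# direct O(n*m) sums, plain loops.

brute_conv <- function(x, h) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    js <- seq_len(min(i, length(h)))
    out[i] <- sum(h[js] * x[i - js + 1])
  }
  out
}

brute_gamma <- function(tau1, dt, span) {
  t <- seq(0, span, by = dt)
  v <- t * exp(-t / tau1)
  v / sum(v)
}

brute_explp <- function(tau2, dt, span) {
  t <- seq(0, span, by = dt)
  v <- exp(-t / tau2)
  v / sum(v)
}

# Direct delayed-normalization computation (monophasic IRF, no shift/gain).
brute_dn <- function(stim_values, tau1, tau2, n, sigma, dt) {
  irf <- brute_gamma(tau1, dt, max(8 * tau1, 1.2))
  h2 <- brute_explp(tau2, dt, max(5 * tau2, 1.2))
  rl <- abs(brute_conv(stim_values, irf))
  pool <- brute_conv(rl, h2)
  rl ^ n / (sigma ^ n + pool ^ n)
}

fig2_defaults <- function(...) {
  args <- utils::modifyList(list(tau1 = 0.05, w = 0, tau2 = 0.1, n = 2,
                                 sigma = 1), list(...))
  do.call(dn_params, args)
}
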