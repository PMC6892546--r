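test_that("full model matches the brute-force reference implementation", {
  stim <- stim_step(0.5, 1.2)
  r <- dn_response(stim, dn_params(tau1 = 0.07, w = 0, tau2 = 0.15, n = 2.2,
                                   sigma = 0.3))
  oracle <- brute_dn(stim$values, 0.07, 0.15, 2.2, 0.3, 0.001)
  expect_equal(r$values, oracle, tolerance = 1e-8)
  expect_equal(r$stage, "normalized")
})

test_that("maximally biphasic model returns to zero for a sustained stimulus", {
  r <- dn_response(stim_step(2, 2), fig2_defaults(w = 1))
  tail_mean <- mean(r$values[1901:2000])
  expect_lt(abs(tail_mean), 1e-6 * max(r$values))
})

test_that("steady state for constant contrast follows c^n / (sigma^n + c^n)", {
  for (cc in c(0.25, 0.5, 1)) {
    for (g in c(1, 2.5)) {
      r <- dn_response(stim_step(3, 3, contrast = cc),
                       fig2_defaults(gain = g))
      ss <- mean(r$values[2901:3000])
      expect_equal(ss, g * cc^2 / (1 + cc^2), tolerance = 0.005)
    }
  }
})

test_that("sustained response has a transient exceeding the sustained level", {
  r <- dn_response(stim_step(0.5, 1), fig2_defaults())
  sustained <- mean(r$values[401:500])  # last 100 ms of stimulation
  expect_gt(max(r$values), sustained)
})

test_that("large sigma reduces the model to the scaled LN response", {
  stim <- stim_step(0.5, 1)
  p <- fig2_defaults(sigma = 1e6, gain = 3)
  r <- dn_response(stim, p)
  irf <- make_biphasic_irf(p$tau1, p$w, dt = 0.001)
  ln <- 3 * abs(delaynorm:::convolve_causal(stim$values, irf$values))^2 / 1e12
  on <- r$values > 1e-20
  expect_lt(max(abs(r$values[on] - ln[on]) / ln[on]), 1e-3)
})

test_that("sigma = 0 is guarded for silent input and flagged otherwise", {
  grid <- time_grid(n = 100)
  silent <- stimulus_timecourse(numeric(100), grid)
  r <- dn_response(silent, fig2_defaults(sigma = 1e-12))
  expect_equal(r$values, numeric(100))
  r0 <- suppressWarnings(dn_response(silent, dn_params(sigma = 0)))
  expect_equal(r0$values, numeric(100))
  expect_warning(dn_response(stim_step(0.05, 0.1), dn_params(sigma = 0)),
                 "sigma = 0")
})

test_that("shift delays the output and gain scales it", {
  stim <- stim_step(0.3, 0.8)
  base <- dn_response(stim, fig2_defaults())
  shifted <- dn_response(stim, fig2_defaults(shift = 0.02, gain = 2))
  expect_equal(shifted$values[21:800], 2 * base$values[1:780],
               tolerance = 1e-10)
  expect_equal(shifted$values[1:20], numeric(20))
})

test_that("denominator variants differ only in pool exponent placement", {
  stim <- stim_step(0.5, 1)
  p <- fig2_defaults(sigma = 0.5)
  a <- dn_response(stim, p, denominator = "low_pass_then_power")
  b <- dn_response(stim, p, denominator = "power_then_low_pass")
  expect_false(isTRUE(all.equal(a$values, b$values)))
  # with n = 1 the two variants coincide
  p1 <- fig2_defaults(n = 1, sigma = 0.5)
  expect_equal(dn_response(stim, p1)$values,
               dn_response(stim, p1, "power_then_low_pass")$values,
               tolerance = 1e-10)
})

test_that("peak amplitude rises and peak latency falls with contrast", {
  p <- dn_params(tau1 = 0.05, w = 0, tau2 = 0.1, n = 2, sigma = 0.15)
  contrasts <- seq(0.1, 0.9, by = 0.1)
  resps <- lapply(contrasts, function(cc) {
    dn_response(stim_step(0.5, 1, contrast = cc), p)
  })
  cd <- contrast_dynamics(resps, contrasts)
  expect_true(all(diff(cd$peak_amp) >= -1e-12))
  expect_true(all(diff(cd$peak_time) <= 1e-12))
})

test_that("cascading reproduces one stage exactly and delays the peak", {
  stim <- stim_step(0.5, 1)
  p <- fig2_defaults()
  expect_identical(cascade_dn(stim, p, 1)$values, dn_response(stim, p)$values)
  one <- dn_response(stim, p)$values
  two <- cascade_dn(stim, p, 2)$values
  expect_gt(which.max(two), which.max(one))
  # zero input propagates
  z <- stimulus_timecourse(numeric(1000), stim$grid)
  expect_equal(cascade_dn(z, p, 3)$values, numeric(1000))
  expect_error(cascade_dn(stim, p, 0), "n_stages")
})

test_that("summary metrics locate the peak and the asymptote", {
  grid <- time_grid(n = 500)
  v <- numeric(500); v[120] <- 2; v[500] <- 1
  r <- response_timecourse(v, grid, "measured")
  m <- summarize_dynamics(r, shift = 0.01, stim_onset = 0, stim_offset = 0.5)
  expect_equal(m$t_peak, 119 * 0.001 - 0.01)
  expect_equal(m$peak_amplitude, 2)
  const <- response_timecourse(rep(3, 500), grid, "measured")
  expect_equal(summarize_dynamics(const, 0, 0, 0.5)$r_asymp, 1)
  expect_error(summarize_dynamics(response_timecourse(numeric(500), grid),
                                  0, 0, 0.5),
               "undefined")
})

test_that("r_asymp agrees with an independent tail-over-peak computation", {
  stim <- stim_step(0.5, 2)
  r <- dn_response(stim, fig2_defaults())
  m <- summarize_dynamics(r, shift = 0, stim_onset = 0, stim_offset = 0.5)
  oracle <- brute_dn(stim$values, 0.05, 0.1, 2, 1, 0.001)
  t <- grid_times(stim$grid)
  expect_equal(m$r_asymp,
               mean(oracle[t >= 0.4 & t <= 0.5]) / max(oracle),
               tolerance = 1e-6)
})
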