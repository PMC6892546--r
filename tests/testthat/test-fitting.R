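test_that("variance explained is the squared Pearson correlation", {
  set.seed(2)
  d <- stats::rnorm(200)
  expect_equal(variance_explained(d, d), 1)
  expect_equal(variance_explained(3 * d + 5, d), 1)
  # orthogonal to the mean-centered data
  o <- stats::rnorm(200)
  o <- o - mean(o)
  o <- o - d * sum(o * (d - mean(d))) / sum((d - mean(d))^2)
  expect_equal(variance_explained(o, d), 0, tolerance = 1e-12)
  expect_error(variance_explained(d, rep(1, 200)), "constant")
  expect_equal(variance_explained(rep(1, 200), d), 0)
})

test_that("profiled gain equals the closed-form least-squares slope", {
  set.seed(3)
  p <- abs(stats::rnorm(100))
  d <- 1.7 * p + stats::rnorm(100, sd = 0.01)
  expect_equal(delaynorm:::profile_gain(p, d), sum(p * d) / sum(p * p))
  # negative slopes are clamped to the positive floor
  expect_equal(delaynorm:::profile_gain(p, -d), 1e-8)
})

test_that("grid seeding recovers an interior generating node exactly", {
  rg <- grid_ranges()
  steps <- function(r) seq(r[1], r[2], length.out = 10)
  node <- c(tau1 = steps(rg$tau1)[4], tau2 = steps(rg$tau2)[3],
            n = steps(rg$n)[2], sigma = steps(rg$sigma)[5])
  stim <- stim_step(0.5, 1.2)
  truth <- dn_response(stim, dn_params(tau1 = node[1], w = 0,
                                       tau2 = node[2], n = node[3],
                                       sigma = node[4], gain = 2))
  g <- grid_fit(truth, stim, rg)
  expect_equal(g$seed, node, tolerance = 1e-12)
  expect_equal(g$gain, 2, tolerance = 1e-6)
  expect_equal(g$n_evaluated, 10000L)
  expect_error(grid_fit(rep(0, 1200), stim), "seeding error")
})

test_that("two-stage fit recovers parameters from a two-contrast family", {
  true <- dn_params(tau1 = 0.2, w = 0, tau2 = 0.3, n = 2.5, sigma = 0.12,
                    shift = 0.01, gain = 2)
  stims <- list(stim_step(0.5, 1.2, contrast = 1),
                stim_step(0.5, 1.2, contrast = 0.3))
  data <- lapply(stims, function(s) dn_response(s, true)$values)
  fit <- fit_timecourse(data, stims)
  p <- fit$params
  expect_lt(abs(p$tau1 / true$tau1 - 1), 0.1)
  expect_lt(abs(p$tau2 / true$tau2 - 1), 0.1)
  expect_lt(abs(p$n / true$n - 1), 0.1)
  expect_lt(abs(p$sigma / true$sigma - 1), 0.1)
  expect_gte(fit$r2, 0.999)
  # the seed reported is the grid winner, and refinement cannot be worse
  g <- grid_fit(data, stims)
  expect_equal(fit$seed_used[1:4], unname(g$seed))
  obj_seed <- search_fit(data, stims, g$seed, maxeval = 1,
                         max_restarts = 0)$sse
  expect_lte(fit$sse, obj_seed)
  # shift respects its bounds
  b <- fit_bounds()
  expect_gte(p$shift, b$lower[5])
  expect_lte(p$shift, b$upper[5])
})

test_that("search is a fixed point at its own optimum and validates seeds", {
  true <- dn_params(tau1 = 0.15, w = 0, tau2 = 0.2, n = 2, sigma = 0.1)
  stim <- stim_step(0.5, 1.2)
  data <- dn_response(stim, true)$values
  f1 <- search_fit(data, stim, c(0.15, 0.2, 2, 0.1, 0.001))
  p <- f1$params
  f2 <- search_fit(data, stim, c(p$tau1, p$tau2, p$n, p$sigma, p$shift))
  expect_lt(abs(f2$sse - f1$sse), 1e-8)
  expect_error(search_fit(data, stim, c(0.01, 0.2, 2, 0.1, 0.001)),
               "outside")
})

test_that("median recovery stays within 20% under trial noise", {
  true <- dn_params(tau1 = 0.15, w = 0, tau2 = 0.2, n = 2, sigma = 0.1,
                    gain = 2)
  stim <- stim_step(0.5, 1.2)
  truth <- dn_response(stim, true)$values
  tau1_hat <- vapply(1:6, function(seed) {
    trials <- simulate_observation(true, stim, n_trials = 30,
                                   noise_sd = max(truth) / 10,
                                   rng_seed = seed)
    fit_timecourse(colMeans(trials), stim)$params$tau1
  }, numeric(1))
  expect_lt(abs(stats::median(tau1_hat) / 0.15 - 1), 0.2)
})

test_that("joint contrast-family fit recovers the generating cell", {
  cell <- dn_params(tau1 = 0.04, w = 0, tau2 = 0.1, n = 2, sigma = 0.1,
                    shift = 0.01, gain = 1.5)
  sim <- simulate_contrast_psths(cell, noise_sd = 0)
  fit <- fit_contrast_family(sim$psths, sim$contrasts)
  p <- fit$params
  for (nm in c("tau1", "tau2", "n", "sigma", "gain")) {
    expect_lt(abs(p[[nm]] / cell[[nm]] - 1), 0.1)
  }
  expect_gte(fit$r2, 0.999)
  # fitted model: zero contrast predicts exactly zero
  expect_equal(dn_response(sim$stims[[1]], p)$values,
               numeric(sim$grid$n))
  # fitted model reproduces the contrast-dynamics ordering
  cd <- contrast_dynamics(lapply(sim$stims[-1],
                                 function(s) dn_response(s, p)),
                          sim$contrasts[-1])
  expect_true(all(diff(cd$peak_amp) > 0))
  expect_true(all(diff(cd$peak_time) <= 1e-12))
  expect_error(fit_contrast_family(sim$psths, sim$contrasts * 2), "contrasts")
})

test_that("biphasic electrode fit preserves offset-transient ordering", {
  stim <- stim_step(0.5, 1.2, t0 = -0.2)
  big <- dn_response(stim, dn_params(tau1 = 0.08, w = 0.8, tau2 = 0.1,
                                     n = 2, sigma = 0.1))$values
  small <- dn_response(stim, dn_params(tau1 = 0.08, w = 0.1, tau2 = 0.1,
                                       n = 2, sigma = 0.1))$values
  f_big <- fit_biphasic_electrode(big, stim)
  f_small <- fit_biphasic_electrode(small, stim)
  expect_gt(f_big$params$w, f_small$params$w)
  expect_identical(f_big$params$n, 2)
  # the winning seed is one of the four standard candidates
  defaults <- eval(formals(fit_biphasic_electrode)$seeds)
  expect_true(any(vapply(defaults, identical, logical(1), f_big$seed_used)))
  expect_gte(f_big$r2, 0.99)
})

test_that("scaled-shifted analysis recovers constructed transformations", {
  r <- dn_response(stim_step(0.2, 0.8), fig2_defaults(sigma = 0.1))
  self <- scaled_shifted_fit(r, r)
  expect_equal(self$scale, 1, tolerance = 1e-12)
  expect_equal(self$shift_samples, 0)
  expect_equal(self$r2, 1)
  target <- response_timecourse(
    0.5 * c(numeric(10), r$values)[seq_len(r$grid$n)], r$grid)
  rec <- scaled_shifted_fit(r, target)
  expect_equal(rec$scale, 0.5, tolerance = 1e-10)
  expect_equal(rec$shift, 10 * r$grid$dt)
  expect_error(scaled_shifted_fit(numeric(100), r$values[1:100]),
               "identically zero")
})

test_that("resampling modes are deterministic and statistically sane", {
  stim <- stim_step(0.5, 1.2, t0 = -0.2)
  true <- dn_params(tau1 = 0.1, w = 0, tau2 = 0.12, n = 2, sigma = 0.08,
                    gain = 3)
  trials <- simulate_observation(true, stim, n_trials = 6, noise_sd = 0.3,
                                 rng_seed = 9)
  loo <- resample_fit(trials, stim, "loo_trials")
  expect_equal(loo$n_folds, 6)
  expect_lte(mean(loo$r2_test), mean(loo$r2_train))
  bs1 <- resample_fit(trials[1:3, ], stim, "bootstrap_electrodes",
                      n_draws = 5, rng_seed = 11)
  bs2 <- resample_fit(trials[1:3, ], stim, "bootstrap_electrodes",
                      n_draws = 5, rng_seed = 11)
  expect_identical(bs1$ci_lower, bs2$ci_lower)
  expect_identical(bs1$central, bs2$central)
  expect_error(resample_fit(trials[1, , drop = FALSE], stim, "loo_trials"),
               "at least 2")
})
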