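test_that("band design drops line-noise harmonics and keeps ten bins", {
  b <- design_band_bins(70, 210, 10, 60)
  expect_equal(nrow(b), 10)
  expect_equal(b$f_lo, c(70, 80, 90, 100, 130, 140, 150, 160, 190, 200))
  # no surviving bin contains 120 or 180 Hz
  expect_false(any(b$f_lo <= 120 & b$f_hi >= 120))
  expect_false(any(b$f_lo <= 180 & b$f_hi >= 180))
  # disabling line exclusion restores the contiguous cover
  expect_equal(nrow(design_band_bins(70, 210, 10, 0)), 14)
  # the LFP variant excludes 100 and 150 Hz (50 Hz line)
  lfp <- design_band_bins(85, 175, 10, 50)
  expect_false(any(lfp$f_lo <= 100 & lfp$f_hi >= 100))
  expect_false(any(lfp$f_lo <= 150 & lfp$f_hi >= 150))
  expect_error(design_band_bins(55, 65, 10, 60), "design error")
})

test_that("band envelope isolates in-band power", {
  fs <- 1000; n <- 1200; tt <- (0:(n - 1)) / fs
  x <- 2 * sin(2 * pi * 75 * tt)
  mid <- 300:900
  inband <- bandpass_envelope(x, c(70, 80), fs)
  outband <- bandpass_envelope(x, c(130, 140), fs)
  expect_equal(mean(inband[mid]), 4, tolerance = 0.05)    # A^2 for A = 2
  expect_lt(mean(outband[mid]), 0.001 * 4)
  expect_lt(mean(bandpass_envelope(rep(1, n), c(70, 80), fs)[mid]), 1e-6)
  # amplitude-modulated carrier: envelope power tracks the squared modulator
  env <- 1 + 0.8 * sin(2 * pi * 3 * tt)
  am <- env * sin(2 * pi * 75 * tt)
  p <- bandpass_envelope(am, c(70, 80), fs)
  expect_gt(stats::cor(p[100:1100], env[100:1100]^2), 0.95)
  expect_error(bandpass_envelope(x, c(480, 495), fs), "Nyquist")
})

test_that("geometric-mean band combination favors low-power bands", {
  x <- abs(stats::rnorm(50)) + 0.1
  expect_equal(combine_bands(rbind(x, x, x)), x, tolerance = 1e-12)
  a <- stats::runif(50) + 0.5; b <- stats::runif(50) + 0.5
  expect_equal(combine_bands(rbind(a, b)), sqrt(a * b), tolerance = 1e-12)
  # one dominant band pulls the geometric mean far less than the arithmetic
  small <- matrix(1, 3, 10); big <- rbind(small, 100)
  gm <- combine_bands(big); am <- colMeans(big)
  expect_true(all(abs(gm - 1) < abs(am - 1)))
  expect_error(combine_bands(rbind(a, -b)), "nonnegative")
})

test_that("epoch normalization zeroes the baseline and scales correctly", {
  fs <- 1000; n <- 1200
  t <- -0.2 + (0:(n - 1)) / fs
  base <- 2
  bb <- array(0, c(2, 4, n))
  bb[1, , ] <- matrix(rep(ifelse(t >= 0 & t < 0.5, 2 * base, base), 4),
                      4, byrow = TRUE)
  bb[2, , ] <- base  # flat electrode
  attr(bb, "fs") <- fs; attr(bb, "t0") <- -0.2
  norm <- epoch_normalize(bb)
  expect_equal(max(norm$values[1, t >= 0.1 & t < 0.4]), 1)  # 2x baseline -> 1
  expect_equal(norm$values[2, ], numeric(n))
  bidx <- t >= -0.2 & t < 0
  expect_lt(max(abs(rowMeans(norm$values[, bidx]))), 1e-12)
  bad <- bb; bad[1, , ] <- 0
  expect_error(epoch_normalize(bad), "normalization error")
})

test_that("electrode selection applies both response criteria", {
  fs <- 1000; n <- 1200
  t <- -0.2 + (0:(n - 1)) / fs
  stim_on <- t >= 0 & t < 0.5
  mk <- function(peak_mult, mean_mult) {
    v <- rep(1, n)
    v[stim_on] <- mean_mult
    v[which(stim_on)[1:50]] <- peak_mult
    v
  }
  bb <- array(0, c(3, 2, n))
  bb[1, , ] <- matrix(rep(mk(3, 1.5), 2), 2, byrow = TRUE)   # keep
  bb[2, , ] <- matrix(rep(mk(1.4, 1.2), 2), 2, byrow = TRUE) # peak too low
  bb[3, , ] <- matrix(rep(mk(1.6, 0.5), 2), 2, byrow = TRUE) # mean below baseline
  attr(bb, "fs") <- fs; attr(bb, "t0") <- -0.2
  keep <- select_electrodes(epoch_normalize(bb))
  expect_equal(keep, c(TRUE, FALSE, FALSE))
})

test_that("eccentricity bins split at 5 and 10 degrees", {
  expect_equal(as.character(bin_by_eccentricity(c(3, 7, 12))),
               c("foveal", "middle", "peripheral"))
  expect_equal(as.character(bin_by_eccentricity(c(5, 10))),
               c("middle", "middle"))
  expect_error(bin_by_eccentricity(-1), "nonnegative")
})

test_that("broadband power is scale covariant and its normalization invariant", {
  n <- 1200
  t <- -0.2 + (0:(n - 1)) / 1000
  env <- ifelse(t >= 0 & t < 0.5, 1.5, 0.5)
  v <- simulate_voltage(env, n_electrodes = 1, n_trials = 3, rng_seed = 21)
  v2 <- voltage_epochs(3 * v$values, fs = v$fs, t0 = v$t0)
  bands <- design_band_bins()[1:3, ]
  bb1 <- extract_broadband(v, bands)
  bb2 <- extract_broadband(v2, bands)
  expect_equal(bb2, 9 * bb1, tolerance = 1e-6, ignore_attr = TRUE)
  n1 <- epoch_normalize(bb1); n2 <- epoch_normalize(bb2)
  expect_equal(n1$values, n2$values, tolerance = 1e-6)
})
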