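#' Variance explained (squared Pearson correlation)
#'
#' Model accuracy throughout the package is summarized as r^2, the square of
#' the Pearson correlation between prediction and data. The metric is
#' invariant to affine rescaling of either argument.
#'
#' @param pred,data Numeric vectors (or response objects) of equal length.
#' @return r^2 in [0, 1]. A constant prediction yields 0; constant data is
#'   an error (the metric is undefined).
#' @export
variance_explained <- function(pred, data) {
  p <- as_values(pred)
  d <- as_values(data)
  stopifnot(length(p) == length(d))
  if (stats::sd(d) == 0) stop("variance explained is undefined for constant data")
  if (stats::sd(p) == 0) return(0)
  stats::cor(p, d) ^ 2
}

#' Grid ranges for seed search
#'
#' Defaults: tau1 and tau2 in [0.07, 1] s, n in [1, 6], sigma in
#' [0.01, 0.5], each sampled in 10 equal steps (10^4 combinations).
#'
#' @param tau1,tau2,n,sigma Length-2 numeric ranges `c(lo, hi)`.
#' @param n_steps Steps per parameter (>= 2).
#' @return An object of class `grid_ranges`.
#' @export
grid_ranges <- function(tau1 = c(0.07, 1), tau2 = c(0.07, 1),
                        n = c(1, 6), sigma = c(0.01, 0.5), n_steps = 10) {
  chk <- function(r, nm) {
    if (length(r) != 2L || r[1] >= r[2]) stop("invalid range for ", nm)
    r
  }
  stopifnot(n_steps >= 2)
  structure(list(tau1 = chk(tau1, "tau1"), tau2 = chk(tau2, "tau2"),
                 n = chk(n, "n"), sigma = chk(sigma, "sigma"),
                 n_steps = as.integer(n_steps)),
            class = "grid_ranges")
}

#' Box bounds for the refinement search
#'
#' Defaults over (tau1, tau2, n, sigma, shift): lower
#' `[0.07, 0.07, 1, 0.01, 0.0001]`, upper `[1, 1, 6, 0.5, 0.1]`.
#'
#' @param lower,upper Numeric length-5 vectors.
#' @return An object of class `fit_bounds`.
#' @export
fit_bounds <- function(lower = c(tau1 = 0.07, tau2 = 0.07, n = 1,
                                 sigma = 0.01, shift = 1e-4),
                       upper = c(tau1 = 1, tau2 = 1, n = 6,
                                 sigma = 0.5, shift = 0.1)) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  structure(list(lower = lower, upper = upper), class = "fit_bounds")
}

# --- internal: multi-condition prediction and profiled-gain objective ------

# Normalize (data, stim) to parallel lists of numeric vectors + dt.
as_condition_list <- function(data, stim) {
  if (inherits(stim, "stimulus_timecourse")) stim <- list(stim)
  if (inherits(data, "response_timecourse") || is.numeric(data)) data <- list(data)
  stopifnot(length(data) == length(stim))
  dt <- stim[[1]]$grid$dt
  for (s in stim) stopifnot(inherits(s, "stimulus_timecourse"),
                            abs(s$grid$dt - dt) < 1e-12)
  list(data = lapply(data, as_values),
       stim = lapply(stim, function(s) s$values),
       dt = dt)
}

# DN prediction (gain = 1) per condition, returned concatenated.
# Kernels are precomputed once per parameter vector; conditions share them.
dn_predict_concat <- function(stims, dt, tau1, w, tau2, n, sigma, shift) {
  irf <- make_biphasic_irf(tau1, w, dt = dt)
  h2 <- make_exponential_lowpass(tau2, dt = dt)
  unlist(lapply(stims, function(sv) {
    rl <- abs(convolve_causal(sv, irf$values))
    pool <- pmax(convolve_causal(rl, h2$values), 0) ^ n
    r <- rl ^ n / (sigma ^ n + pool)
    apply_shift(r, shift, dt)
  }))
}

# Least-squares gain of data on prediction (through the origin), clamped to
# a small positive floor so the model never flips sign.
profile_gain <- function(pred, data) {
  ss <- sum(pred ^ 2)
  if (ss == 0) return(0)
  max(sum(pred * data) / ss, 1e-8)
}

#' Grid seed search
#'
#' Evaluates the forward model (with `w = 0`, `shift = 0`) at every node of
#' the parameter grid, solves the output gain per node by least-squares
#' regression of the data on the prediction, and returns the node with the
#' highest variance explained. With the default ranges this evaluates
#' exactly 10^4 parameter combinations. Ties are broken in favor of the
#' first node in lexicographic (tau1, tau2, n, sigma) order.
#'
#' @param data A `response_timecourse` (or numeric vector), or a list of
#'   them for a joint multi-condition fit.
#' @param stim Matching `stimulus_timecourse` or list thereof.
#' @param ranges A `grid_ranges` object.
#' @return A list with `seed` (named vector tau1, tau2, n, sigma), `gain`,
#'   `r2`, and `n_evaluated`.
#' @export
grid_fit <- function(data, stim, ranges = grid_ranges()) {
  cl <- as_condition_list(data, stim)
  d <- unlist(cl$data)
  if (stats::sd(d) == 0) stop("seeding error: data time course is constant")
  steps <- function(r) seq(r[1], r[2], length.out = ranges$n_steps)
  tau1s <- steps(ranges$tau1); tau2s <- steps(ranges$tau2)
  ns <- steps(ranges$n); sigmas <- steps(ranges$sigma)

  # Factorized evaluation: the rectified linear drive depends only on tau1,
  # and the pooled drive only on (tau1, tau2); exponent and sigma act
  # pointwise on those.
  best <- list(r2 = -Inf)
  n_eval <- 0L
  for (tau1 in tau1s) {
    irf <- make_biphasic_irf(tau1, 0, dt = cl$dt)
    rls <- lapply(cl$stim, function(sv) abs(convolve_causal(sv, irf$values)))
    for (tau2 in tau2s) {
      h2 <- make_exponential_lowpass(tau2, dt = cl$dt)
      pools <- lapply(rls, function(rl) pmax(convolve_causal(rl, h2$values), 0))
      rl_cat <- unlist(rls); pool_cat <- unlist(pools)
      for (nexp in ns) {
        num <- rl_cat ^ nexp
        pooln <- pool_cat ^ nexp
        for (sigma in sigmas) {
          n_eval <- n_eval + 1L
          pred <- num / (sigma ^ nexp + pooln)
          if (stats::sd(pred) == 0) next
          r2 <- stats::cor(pred, d) ^ 2
          if (r2 > best$r2) {
            best <- list(seed = c(tau1 = tau1, tau2 = tau2, n = nexp,
                                  sigma = sigma),
                         gain = profile_gain(pred, d), r2 = r2)
          }
        }
      }
    }
  }
  if (!is.finite(best$r2)) stop("seeding error: all grid predictions are constant")
  best$n_evaluated <- n_eval
  best
}

# --- bounded derivative-free search ---------------------------------------

# Box-bounded Nelder-Mead via the sine transform
# x = lo + (hi - lo) * (sin(u) + 1) / 2 on unconstrained u.
fminsearch_bounded <- function(fn, x0, lower, upper,
                               tol = 1e-6, maxeval = 5000) {
  stopifnot(all(x0 >= lower - 1e-12), all(x0 <= upper + 1e-12))
  x0 <- pmin(pmax(x0, lower), upper)
  to_u <- function(x) asin(pmin(pmax(2 * (x - lower) / (upper - lower) - 1,
                                     -1), 1))
  to_x <- function(u) lower + (upper - lower) * (sin(u) + 1) / 2
  opt <- stats::optim(to_u(x0), function(u) fn(to_x(u)),
                      method = "Nelder-Mead",
                      control = list(maxit = maxeval, reltol = tol,
                                     warn.1d.NelderMead = FALSE))
  list(par = unname(to_x(opt$par)), value = opt$value,
       counts = opt$counts[["function"]],
       converged = opt$convergence == 0)
}

# Simplex searches stall on narrow valleys (and on the sample-quantized
# shift dimension), so the search is restarted from its own optimum until
# the objective stops improving.
run_search <- function(objective, seed, lower, upper, tol, maxeval,
                       max_restarts) {
  opt <- fminsearch_bounded(objective, seed, lower, upper, tol, maxeval)
  total <- opt$counts
  for (k in seq_len(max_restarts)) {
    prev <- opt$value
    opt2 <- fminsearch_bounded(objective, opt$par, lower, upper, tol, maxeval)
    total <- total + opt2$counts
    if (opt2$value < opt$value) opt <- opt2
    if (prev - opt2$value <= tol * max(1, abs(prev))) break
  }
  opt$counts <- total
  opt
}

new_fit_result <- function(params, r2, sse, seed_used, n_iterations,
                           converged) {
  structure(list(params = params, r2 = r2, sse = sse, seed_used = seed_used,
                 n_iterations = n_iterations, converged = converged),
            class = "dn_fit")
}

#' @export
print.dn_fit <- function(x, ...) {
  cat(sprintf("<dn_fit> r2 = %.4f, sse = %.4g, %s (%d evaluations)\n",
              x$r2, x$sse,
              if (x$converged) "converged" else "not converged",
              x$n_iterations))
  print(x$params)
  invisible(x)
}

#' Refinement search from a seed
#'
#' Minimizes the squared error between the shifted, scaled model prediction
#' and the data over (tau1, tau2, n, sigma, shift) within box bounds, using
#' a derivative-free simplex search with the bounds enforced by a sine
#' transform. The output gain is profiled out by least squares at every
#' objective evaluation, so it is never a free search dimension. `w` is held
#' at 0 (see [fit_biphasic_electrode()] for the biphasic variant).
#'
#' @inheritParams grid_fit
#' @param seed Named or positional numeric seed for (tau1, tau2, n, sigma)
#'   or (tau1, tau2, n, sigma, shift); a missing shift starts at the lower
#'   bound.
#' @param bounds A `fit_bounds` object; the seed must lie within it.
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param maxeval Maximum objective evaluations per simplex run
#'   (default 5000).
#' @param max_restarts Maximum simplex restarts from the current optimum
#'   (default 8); the search stops early once a restart no longer improves
#'   the objective.
#' @return A `dn_fit` with the fitted `dn_params`, `r2`, `sse`, the seed,
#'   evaluation count, and a convergence flag.
#' @export
search_fit <- function(data, stim, seed, bounds = fit_bounds(),
                       tol = 1e-6, maxeval = 5000, max_restarts = 8) {
  cl <- as_condition_list(data, stim)
  d <- unlist(cl$data)
  seed <- unname(unlist(seed))
  if (length(seed) == 4L) seed <- c(seed, unname(bounds$lower[5]))
  stopifnot(length(seed) == 5L)
  if (any(seed < bounds$lower - 1e-12) || any(seed > bounds$upper + 1e-12)) {
    stop("seed lies outside the fit bounds")
  }
  objective <- function(x) {
    pred <- dn_predict_concat(cl$stim, cl$dt, tau1 = x[1], w = 0,
                              tau2 = x[2], n = x[3], sigma = x[4],
                              shift = x[5])
    g <- profile_gain(pred, d)
    sum((g * pred - d) ^ 2)
  }
  opt <- run_search(objective, seed, bounds$lower, bounds$upper,
                    tol = tol, maxeval = maxeval,
                    max_restarts = max_restarts)
  x <- opt$par
  pred <- dn_predict_concat(cl$stim, cl$dt, tau1 = x[1], w = 0, tau2 = x[2],
                            n = x[3], sigma = x[4], shift = x[5])
  g <- profile_gain(pred, d)
  params <- dn_params(tau1 = x[1], w = 0, tau2 = x[2], n = x[3],
                      sigma = x[4], shift = x[5], gain = g)
  new_fit_result(params,
                 r2 = variance_explained(g * pred, d),
                 sse = sum((g * pred - d) ^ 2),
                 seed_used = seed, n_iterations = opt$counts,
                 converged = opt$converged)
}

#' Two-stage fit: grid seeding followed by refinement
#'
#' The standard estimation procedure: evaluate the full parameter grid to
#' find the best seed, then refine with the bounded simplex search. The
#' composition is deterministic given its inputs.
#'
#' @inheritParams search_fit
#' @param ranges A `grid_ranges` for the seeding stage.
#' @return A `dn_fit`; `seed_used` holds the winning grid node.
#' @export
fit_timecourse <- function(data, stim, ranges = grid_ranges(),
                           bounds = fit_bounds(), tol = 1e-6,
                           maxeval = 5000, max_restarts = 8) {
  g <- grid_fit(data, stim, ranges)
  search_fit(data, stim, seed = g$seed, bounds = bounds, tol = tol,
             maxeval = maxeval, max_restarts = max_restarts)
}

#' Joint fit to a contrast family of response time courses
#'
#' Fits a single parameter set (tau1, tau2, n, sigma, shift, gain) to all
#' responses at once, with the input stimulus scaled by each condition's
#' contrast and the squared error summed across conditions. The search is
#' started from each supplied seed and the best result kept.
#'
#' @param psths List of `response_timecourse` objects (or numeric vectors),
#'   one per contrast condition, on a common grid.
#' @param contrasts Numeric contrast levels in [0, 1], one per response.
#' @param stim_duration Stimulus-on duration in seconds (default 0.2).
#' @param stim_onset Stimulus onset time in seconds (default 0).
#' @param dt Sample interval when `psths` are bare vectors (default 1 ms).
#' @param seeds List of numeric seeds (tau1, tau2, n, sigma, shift);
#'   defaults to the two standard starting points
#'   `c(0.1, 0.1, 2, 0.2, 0.03)` and `c(0.1, 0.1, 3, 0.1, 0.04)`.
#' @param bounds,tol,maxeval,max_restarts As in [search_fit()]. Single-cell
#'   time constants run shorter than field-potential ones, so the default
#'   bounds here are wide (tau1 down to 5 ms, n up to 10), standing in for
#'   the historically unbounded search.
#' @return A `dn_fit` for the jointly fitted model.
#' @export
fit_contrast_family <- function(psths, contrasts, stim_duration = 0.2,
                                stim_onset = 0, dt = 0.001,
                                seeds = list(c(0.1, 0.1, 2, 0.2, 0.03),
                                             c(0.1, 0.1, 3, 0.1, 0.04)),
                                bounds = fit_bounds(
                                  lower = c(tau1 = 0.005, tau2 = 0.01,
                                            n = 0.5, sigma = 0.001,
                                            shift = 1e-4),
                                  upper = c(tau1 = 1, tau2 = 1, n = 10,
                                            sigma = 1, shift = 0.1)),
                                tol = 1e-6, maxeval = 5000,
                                max_restarts = 8) {
  if (any(contrasts < 0 | contrasts > 1)) {
    stop("contrasts must lie within [0, 1]")
  }
  nlen <- length(as_values(psths[[1]]))
  if (inherits(psths[[1]], "response_timecourse")) {
    grid <- psths[[1]]$grid
  } else {
    grid <- time_grid(dt = dt, n = nlen, t0 = 0)
  }
  t <- grid_times(grid)
  base <- ifelse(t >= stim_onset & t < stim_onset + stim_duration, 1, 0)
  stims <- lapply(contrasts, function(cc) stimulus_timecourse(cc * base, grid))
  fits <- lapply(seeds, function(s) {
    search_fit(psths, stims, seed = s, bounds = bounds, tol = tol,
               maxeval = maxeval, max_restarts = max_restarts)
  })
  best <- fits[[which.min(vapply(fits, function(f) f$sse, numeric(1)))]]
  best
}

#' Per-electrode fit with a biphasic impulse response
#'
#' For electrodes with prominent stimulus-offset transients the negative
#' lobe weight `w` is estimated rather than fixed at 0. For tractability the
#' exponent is fixed at `n = 2` and the negative-lobe peak at `1.5 * tau1`.
#' Four standard seed sets over (tau1, w, tau2, sigma, shift) — differing in
#' the extent of normalization and of the offset transient — are each
#' refined by the bounded simplex search and the best result by squared
#' error is returned (refining every seed, rather than only the best
#' seed prediction, guards against the offset-transient local optima this
#' objective is prone to).
#'
#' @inheritParams search_fit
#' @param seeds List of numeric length-5 seeds (tau1, w, tau2, sigma,
#'   shift); defaults to the four standard sets.
#' @param lower,upper Box bounds over (tau1, w, tau2, sigma, shift).
#' @return A `dn_fit` whose params have `n = 2` and fitted `w`.
#' @export
fit_biphasic_electrode <- function(data, stim,
                                   seeds = list(
                                     c(0.02, 0.8, 0.15, 0.1, 0.05),
                                     c(0.03, 0.8, 0.1, 0.2, 0.05),
                                     c(0.02, 0.4, 0.15, 0.1, 0.05),
                                     c(0.03, 0.4, 0.1, 0.2, 0.05)),
                                   lower = c(0.005, 0, 0.01, 0.001, 1e-4),
                                   upper = c(0.5, 1, 1, 1, 0.1),
                                   tol = 1e-6, maxeval = 5000,
                                   max_restarts = 8) {
  cl <- as_condition_list(data, stim)
  d <- unlist(cl$data)
  objective <- function(x) {
    pred <- dn_predict_concat(cl$stim, cl$dt, tau1 = x[1], w = x[2],
                              tau2 = x[3], n = 2, sigma = x[4], shift = x[5])
    g <- profile_gain(pred, d)
    sum((g * pred - d) ^ 2)
  }
  opts <- lapply(seeds, function(s) {
    run_search(objective, s, lower, upper, tol = tol, maxeval = maxeval,
               max_restarts = max_restarts)
  })
  ibest <- which.min(vapply(opts, function(o) o$value, numeric(1)))
  opt <- opts[[ibest]]
  seed <- seeds[[ibest]]
  x <- opt$par
  pred <- dn_predict_concat(cl$stim, cl$dt, tau1 = x[1], w = x[2],
                            tau2 = x[3], n = 2, sigma = x[4], shift = x[5])
  g <- profile_gain(pred, d)
  params <- dn_params(tau1 = x[1], w = x[2], tau2 = x[3], n = 2,
                      sigma = x[4], shift = x[5], gain = g)
  new_fit_result(params,
                 r2 = variance_explained(g * pred, d),
                 sse = sum((g * pred - d) ^ 2),
                 seed_used = seed, n_iterations = opt$counts,
                 converged = opt$converged)
}

#' Scaled-and-shifted-copy approximation
#'
#' Tests whether one response time course is an (integer-sample) shifted and
#' nonnegatively scaled copy of a reference: for every candidate shift the
#' optimal scale is solved in closed form and the best (shift, scale) pair
#' by squared error is returned together with the variance it explains.
#'
#' @param reference,target `response_timecourse` objects (or numeric
#'   vectors) on equal grids.
#' @param max_shift Maximum shift magnitude in samples (default: half the
#'   signal length).
#' @return A list with `scale`, `shift` (seconds; positive = reference moved
#'   later), `shift_samples`, and `r2`.
#' @export
scaled_shifted_fit <- function(reference, target, max_shift = NULL) {
  r <- as_values(reference)
  d <- as_values(target)
  stopifnot(length(r) == length(d))
  if (all(r == 0)) stop("reference time course is identically zero")
  dt <- if (inherits(reference, "response_timecourse")) reference$grid$dt else 1
  n <- length(r)
  if (is.null(max_shift)) max_shift <- floor(n / 2)
  best <- list(sse = Inf)
  for (k in seq(-max_shift, max_shift)) {
    shifted <- if (k >= 0) c(rep(0, k), r)[seq_len(n)]
    else c(r[-seq_len(-k)], rep(0, -k))
    ss <- sum(shifted ^ 2)
    if (ss == 0) next
    a <- max(sum(shifted * d) / ss, 0)
    sse <- sum((a * shifted - d) ^ 2)
    if (sse < best$sse) {
      best <- list(scale = a, shift_samples = k, sse = sse,
                   pred = a * shifted)
    }
  }
  list(scale = best$scale, shift = best$shift_samples * dt,
       shift_samples = best$shift_samples,
       r2 = variance_explained(best$pred, d))
}

#' Bootstrap and leave-one-out resampling of fits
#'
#' * `bootstrap_electrodes`: draws electrodes with replacement `n_draws`
#'   times (default 100), refits the model to each draw's mean time course,
#'   and reports the per-timepoint 50% confidence interval (25th-75th
#'   percentile) of the fitted predictions.
#' * `loo_trials` / `loo_electrodes`: one fold per unit; the model is fit to
#'   the mean of the remaining units and scored (r^2) on the held-out unit.
#'
#' Identical draws are fit once and reused (the fit is a pure function of
#' the averaged time course), so e.g. duplicated electrodes cost nothing.
#'
#' @param responses Numeric matrix, units (electrodes or trials) x time.
#' @param stim The shared `stimulus_timecourse`.
#' @param mode One of `"bootstrap_electrodes"`, `"loo_trials"`,
#'   `"loo_electrodes"`.
#' @param n_draws Bootstrap draws (default 100; ignored for LOO modes).
#' @param rng_seed Integer seed; identical inputs and seed give identical
#'   results.
#' @param ranges,bounds,tol,maxeval Passed to the underlying fits.
#' @return A list of class `dn_resample` with `mode`, `fits` (per draw or
#'   fold), `predictions` (draws x time, bootstrap mode), `ci_lower`,
#'   `ci_upper`, `ci_level = 0.5`, `central` (per-timepoint median
#'   prediction), `r2_train`, and for LOO modes `r2_test` per fold and
#'   `n_folds`.
#' @export
resample_fit <- function(responses, stim,
                         mode = c("bootstrap_electrodes", "loo_trials",
                                  "loo_electrodes"),
                         n_draws = 100, rng_seed = 1,
                         ranges = grid_ranges(), bounds = fit_bounds(),
                         tol = 1e-6, maxeval = 5000) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(responses))
  n_units <- nrow(responses)
  if (n_units < 2) stop("resampling error: need at least 2 units")

  cache_keys <- list()
  cache_fits <- list()
  fit_mean <- function(avg) {
    for (i in seq_along(cache_keys)) {
      if (identical(cache_keys[[i]], avg)) return(cache_fits[[i]])
    }
    f <- fit_timecourse(avg, stim, ranges = ranges, bounds = bounds,
                        tol = tol, maxeval = maxeval)
    cache_keys[[length(cache_keys) + 1]] <<- avg
    cache_fits[[length(cache_fits) + 1]] <<- f
    f
  }
  predict_fit <- function(f) dn_response(stim, f$params)$values

  if (mode == "bootstrap_electrodes") {
    set.seed(rng_seed)
    draws <- replicate(n_draws, sample.int(n_units, n_units, replace = TRUE),
                       simplify = FALSE)
    fits <- lapply(draws, function(idx) fit_mean(colMeans(responses[idx, ,
                                                                    drop = FALSE])))
    preds <- do.call(rbind, lapply(fits, predict_fit))
    qs <- apply(preds, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
    structure(list(mode = mode, fits = fits, predictions = preds,
                   ci_lower = qs[1, ], central = qs[2, ], ci_upper = qs[3, ],
                   ci_level = 0.5,
                   r2_train = vapply(fits, function(f) f$r2, numeric(1)),
                   n_draws = n_draws, rng_seed = rng_seed),
              class = "dn_resample")
  } else {
    folds <- seq_len(n_units)
    fits <- vector("list", n_units)
    r2_test <- numeric(n_units)
    for (k in folds) {
      avg <- colMeans(responses[-k, , drop = FALSE])
      fits[[k]] <- fit_mean(avg)
      r2_test[k] <- variance_explained(predict_fit(fits[[k]]),
                                       responses[k, ])
    }
    structure(list(mode = mode, fits = fits, r2_test = r2_test,
                   r2_train = vapply(fits, function(f) f$r2, numeric(1)),
                   n_folds = n_units, rng_seed = rng_seed),
              class = "dn_resample")
  }
}

#' @export
print.dn_resample <- function(x, ...) {
  if (x$mode == "bootstrap_electrodes") {
    cat(sprintf("<dn_resample> %s: %d draws, median train r2 = %.3f\n",
                x$mode, x$n_draws, stats::median(x$r2_train)))
  } else {
    cat(sprintf("<dn_resample> %s: %d folds, median held-out r2 = %.3f\n",
                x$mode, x$n_folds, stats::median(x$r2_test)))
  }
  invisible(x)
}
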