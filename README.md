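# delaynorm

Forward modeling and estimation of neuronal temporal dynamics with a
**delayed divisive normalization** model.

Visual neurons respond to a static image with characteristic dynamics: a
large onset transient that decays to a lower sustained level, sub-additive
summation over stimulus duration, suppressed responses to quickly repeated
stimuli, and slower, smaller responses at low contrast. `delaynorm`
implements a compact Linear–Nonlinear–Gain-control model that produces all
of these behaviors from a single mechanism — a divisive gain signal that is
a *delayed* (low-pass filtered) copy of the driving signal — together with
everything needed to exercise it end to end: comparison models, two-stage
parameter estimation, resampling, broadband envelope extraction from raw
field-potential voltage, BOLD amplitude prediction, and synthetic data
generators. It is aimed at researchers modeling ECoG/LFP broadband time
courses, single-unit PSTHs, or fMRI amplitudes for briefly presented static
stimuli.

## The model

The input is a stimulus contrast time course S(t) ∈ [0, 1]. Three stages
produce the response:

1. **Linear.** Convolve with a temporal impulse response
   h1(t) = g(t; τ1) − w · g(t; 1.5 τ1), a weighted difference of two unit-sum
   gamma kernels g(t; τ) ∝ t e^(−t/τ). τ1 sets the summation window
   (g peaks at t = τ1); w ∈ [0, 1] sets the size of the offset transient.
2. **Nonlinear.** Full-wave rectify and exponentiate: |R_L|^n, n > 1.
3. **Gain control.** Divide by a semi-saturation constant plus the
   exponentiated *low-passed* drive:

       R(t) = |R_L(t)|^n / ( σ^n + [ (h2 ∗ |R_L|)(t) ]^n ),
       h2(t) ∝ e^(−t/τ2)

   The delay τ2 is what produces the transient-then-sustained shape: at
   onset the numerator leads, then the sluggish pool catches up and pushes
   the response down.

Two nuisance parameters (an onset latency `shift` and an output `gain`)
map the model onto measured signals. For constant contrast c the steady
state has the closed form gain · c^n / (σ^n + c^n).

Estimation follows a two-stage scheme: an exhaustive grid over
(τ1, τ2, n, σ) — 10 steps per parameter, gain solved by linear regression at
every node — seeds a bounded derivative-free simplex search over
(τ1, τ2, n, σ, shift), with gain profiled out at every evaluation. Accuracy
is reported as r², the squared Pearson correlation between prediction and
data.

## Worked example

Simulate 30 noisy trials of a V1-like response to a 500 ms contrast step,
fit the model to the trial average, and summarize its dynamics:

```r
library(delaynorm)

stim   <- stim_step(0.5, 1.2, t0 = -0.2)   # 500 ms step in a 1.2 s epoch
truth  <- dn_params(tau1 = 0.14, w = 0, tau2 = 0.10, n = 2,
                    sigma = 0.05, gain = 3)
trials <- simulate_observation(truth, stim, n_trials = 30,
                               noise_sd = 0.3, rng_seed = 1)

fit <- fit_timecourse(colMeans(trials), stim)
fit
#> <dn_fit> r2 = 0.9999, sse = 3.373, converged (1914 evaluations)
#> <dn_params> tau1 = 0.1394 s, w = 0, tau2 = 0.09944 s, n = 2,
#>             sigma = 0.05046 | shift = 0.0001002 s, gain = 3.015

resp <- dn_response(stim_step(0.5, 1.2), fit$params)
summarize_dynamics(resp, shift = fit$params$shift,
                   stim_onset = 0, stim_offset = 0.5)
#> Tpeak = 115 ms, Rasymp = 0.25
```

The fit recovers the generating parameters (τ1 within half a percent,
gain within half a percent) and the two summary metrics say what they
mean: the modeled response to a sustained stimulus peaks 115 ms after
onset (latency excluded), and settles at 25% of its peak — the signature
of strong delayed gain control.

A command-line front end wrapping the same functions lives at
`inst/cli/dn.R` (subcommands `simulate`, `extract-broadband`, `fit`,
`predict-bold`, `metrics`).

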