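---
title: "Delayed normalization: model, estimation, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed normalization: model, estimation, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaynorm)
```

## The model and its assumptions

`delaynorm` models the time-varying response of a visual neuron or neural
population to a static image whose contrast varies arbitrarily in time.
The input is a contrast time course $S(t) \in [0,1]$ on a uniform grid
(default 1 ms); the output passes through three stages:

$$R_L = S * h_1(\tau_1, w), \qquad
  R(t) = g \cdot \frac{|R_L(t)|^n}{\sigma^n + \big[(h_2(\tau_2) * |R_L|)(t)\big]^n}$$

delayed by an onset latency (`shift`). The impulse response
$h_1 = g(\tau_1) - w\,g(1.5\tau_1)$ is a weighted difference of two
unit-sum gamma kernels $g(t;\tau) \propto t e^{-t/\tau}$ (shape fixed at
2, so each lobe peaks at its time constant). The gain-control pool is the
rectified *linear* drive filtered by a unit-sum exponential decay
$h_2 \propto e^{-t/\tau_2}$ and then exponentiated.

Assumptions worth making explicit:

* **Self-normalization.** Numerator and pool share one driving signal; no
  separate population pool is modeled.
* **Full-wave rectification** is the absolute value — a population-level
  abstraction of paired half-wave rectified units with complementary
  receptive fields.
* **A single expansive exponent** stands in for any cascade of pointwise
  nonlinearities, since $(x^a)^b = x^{ab}$.
* **No spatial structure.** Contrast is a scalar per time point; surround
  effects, receptive-field structure, and motion are out of scope.

Two structural choices were genuinely open and are worth recording:

* **Where the exponent meets the pool.** The pool is filtered first and
  exponentiated second (`dn_response(..., denominator =
  "low_pass_then_power")`), matching the verbal description of the gain
  signal as a delayed copy of the rectified linear drive. The alternative
  — low-pass the already-exponentiated drive — is available as
  `"power_then_low_pass"`; the two coincide at $n = 1$ and differ little
  elsewhere, but they are not identical and the choice is exposed rather
  than hidden.
* **Pool kernel normalization.** $h_2$ is normalized to unit sum, making
  the pool a weighted average of response history. This keeps $\sigma$ in
  contrast-commensurate units and yields the closed-form steady state
  $g\,c^n/(\sigma^n + c^n)$ for constant contrast $c$, which the tests
  verify against long simulations.

## Parameters

| Parameter | Units | Default | Role |
|---|---|---|---|
| `tau1` | s | 0.05 | peak time of the IRF's first lobe; temporal summation window |
| `w` | — | 0 | negative-lobe weight; size of the offset transient |
| `tau2` | s | 0.1 | pool decay; smoothness/delay of gain control |
| `n` | — | 2 | expansive exponent (> 1) |
| `sigma` | contrast | 1 | semi-saturation; contrast of half-saturation |
| `shift` | s | 0 | nuisance onset latency |
| `gain` | response units | 1 | nuisance output scale |

The defaults are the standard simulation set (`w = 0`, `tau1 = 0.05`,
`tau2 = 0.1`, `n = 2`, `sigma = 1`). With `w = 1` the IRF integrates to
zero and the sustained response vanishes; with `w = 0` the steady state is
positive.

Two derived metrics summarize a sustained-stimulus response more robustly
than raw parameters (whose effects trade off): `t_peak`, the
latency-corrected time to peak (summation window), and `r_asymp`, the
asymptote-to-peak ratio (extent of gain control), computed over the final
20% of the stimulus-on window — the averaging window is this package's
choice, since "asymptote" needs an operational definition.

## Estimation

Fitting minimizes squared error between model and trial-averaged time
course(s):

1. **Grid stage.** All $10^4$ combinations of $\tau_1, \tau_2 \in [0.07,1]$,
   $n \in [1,6]$, $\sigma \in [0.01,0.5]$ (10 equal steps each, $w=0$,
   no shift); output gain is solved per node by linear regression and the
   best node by $r^2$ seeds the search. The grid is factorized internally
   ($R_L$ depends only on $\tau_1$; the pool only on $\tau_1,\tau_2$), so
   the full grid costs about a hundred convolutions rather than $10^4$.
2. **Search stage.** A Nelder–Mead simplex, box-bounded through a sine
   transform (lower $[0.07, 0.07, 1, 0.01, 10^{-4}]$, upper
   $[1, 1, 6, 0.5, 0.1]$ over $\tau_1, \tau_2, n, \sigma,$ shift), with
   gain profiled out in closed form at every evaluation and clamped to a
   small positive floor. Tolerance $10^{-6}$, at most 5000 evaluations per
   run. The simplex is restarted from its own optimum (up to 8 times,
   stopping when the objective stops improving): a single run reliably
   stalls in the narrow valley where $n$ and $\sigma$ trade off.

Variants: `fit_contrast_family()` fits one parameter set jointly to a
family of responses at different contrasts (input scaled by contrast,
errors summed, two standard seeds, wide bounds standing in for the
historically unbounded search, since single-cell time constants run well
below the field-potential bounds); `fit_biphasic_electrode()` frees $w$,
fixes $n = 2$, and refines all four standard seed sets, keeping the best —
refining only the most promising seed leaves electrodes with long
summation windows in a spurious high-$w$ optimum. `resample_fit()`
provides electrode bootstrap (100 draws, per-timepoint 25th–75th
percentile envelope) and leave-one-out folds over trials or electrodes;
draws with identical averaged data reuse one fit, which is exact because
the fit is a deterministic function of the averaged time course.

A single stimulus at one contrast cannot pin down $n$ and $\sigma$
separately — both control the decay of the transient. Two contrasts break
the degeneracy ($n$ rescales a response; $\sigma$ reshapes it), which is
why the recovery tests fit two-contrast families.

## Numerical choices

* **Discretization.** 1 ms default; kernels built on $[0, \max(8\tau, 1.2\,\mathrm{s})]$
  for gamma lobes ($8\tau$ captures > 99% of shape-2 gamma mass; $5\tau$
  does not) and $[0, \max(5\tau, 1.2\,\mathrm{s})]$ for the exponential;
  a support error is raised if a user-supplied grid captures < 99% of the
  kernel mass. Convolution is causal, FFT-based, truncated to the signal
  length; kernel samples beyond the signal length are dropped (they cannot
  reach the output) and lengths are padded to powers of two.
* **Latency.** `shift` delays the output by a *linearly interpolated*
  fractional number of samples. A sample-quantized delay makes the
  objective piecewise-constant in `shift` and stalls the simplex; the
  interpolated delay is smooth and agrees with the integer delay at
  multiples of `dt`.
* **Degenerate inputs.** $\sigma = 0$ with a silent stimulus returns zeros
  rather than NaN; $\sigma = 0$ with drive present is allowed but warned.
  Constant data is an error for $r^2$ (undefined) and for seeding; a
  constant prediction scores $r^2 = 0$. Grid ties break toward the first
  node in lexicographic parameter order. Tiny negative pool values from
  FFT round-off are clamped to zero before fractional exponentiation.
* **Instantaneous-normalization limit.** With $\tau_2$ equal to one
  sample the delayed model approaches the compressive temporal summation
  model (`cts_response`); the residual is first-order in `dt`
  (about $4 \times 10^{-3}$ at 1 ms, $7 \times 10^{-4}$ at 0.2 ms on a
  unit-scale step), so limit comparisons are run at 0.2 ms.

## Broadband extraction

The model's target signal for field potentials is time-varying broadband
power, a proxy for aggregate spiking: ten 10-Hz bins spanning 70–210 Hz
(bins containing 60 Hz line harmonics dropped — the full bin list is in
`design_band_bins()`), each bandpass filtered, enveloped (magnitude of the
FFT analytic signal, computed in-package), squared, and combined across
bins by a geometric mean so the low-power high-frequency bins still
contribute. Trial-averaged power is converted to fractional signal change
against the 200 ms pre-stimulus baseline and the baseline is re-zeroed
exactly.

The band filters are order-5 Butterworth bandpasses with design edges
pushed 1 Hz outside each bin, applied forward-backward (zero phase). The
measured double-pass response keeps passband deviation under 3 dB and
attenuation 10 Hz beyond the edges above 60 dB. A note on terminology: a
Butterworth is monotone, so the "ripple" figure is really edge droop;
automatic order selection driven by those same numbers produces
order-16 designs that are numerically unstable in transfer-function form,
hence the fixed order.

## Synthetic data: what it does and does not emulate

The generators produce: (i) model responses plus iid Gaussian noise on
each trial (Gaussian noise is the matched noise model for a squared-error
fit to trial averages); (ii) contrast families (10 contrasts 0–0.9, 200 ms
stimulus) mimicking PSTH experiments; (iii) raw voltage epochs = pink
background + band-limited 70–210 Hz noise amplitude-modulated by a known
envelope + line harmonics, the ground truth for the broadband chain; and
(iv) a 12-electrode demo spanning 4 ROIs × 3 eccentricity bins with graded
true parameters (summation window lengthening and gain control
strengthening from V1 to anterior maps, offset-transient weight growing
from fovea to periphery).

They do **not** emulate: correlated or non-Gaussian trial noise, 1/f drift
in the broadband baseline, cross-electrode correlations, narrowband gamma
oscillations, eye movements, or any spatial stimulus structure. Passing
tests therefore demonstrate correctness of the computations and
recoverability under the stated noise model — not that real cortical data
satisfy the model.

Demo calibration: the demo's generating exponent is held at 2 in every ROI
so that the per-electrode biphasic fit (which fixes $n = 2$) is well
specified; under that constraint the sustained-step time to peak is
anchored at roughly 115 ms (V1) to 146 ms (anterior), while the
asymptote-to-peak ratio sits near 0.25 rather than the ~0.12 a more
compressive ($n > 2$) parameterization would give. The anchors are
generator properties, chosen once; the recovery tests check orderings, not
absolute values.

Problem sizes used in the shipped tests are deliberately modest (1.2 s
epochs at 1 ms, 6–30 trials, 12 electrodes, 100 bootstrap draws, 5–6
replicate seeds for noisy-recovery medians); they are the sizes a desk
check needs, and every quantitative claim in this vignette is one the
tests or the acceptance script actually compute.

## Known limitations

* The fit objective is squared error on trial averages; no per-trial
  likelihood, no hierarchical pooling across electrodes, and uncertainty
  only via bootstrap percentiles.
* The biphasic fit's four-seed multistart is robust in realistic parameter
  territory but the objective has genuine distant local optima; pathological
  combinations (very short summation window with a barely-biphasic IRF) can
  still fit well with wrong $w$.
* The cascade variant rescales each stage's output to a maximum of 1
  before feeding it forward — a convention, since the model's input
  contract is a contrast in $[0,1]$; alternative scalings would change
  later-stage parameters' meaning.
* The two-temporal-channels comparison model uses this package's gamma
  family for its channel filters (monophasic sustained, fully biphasic
  transient); it is a structural stand-in for the historical filter pair,
  adequate for the qualitative contrasts tested (no gain control, hence
  contrast-invariant latency).
* BOLD prediction treats the hemodynamic transform as a single scalar gain
  on the summed neuronal response; amplitudes must already come from a GLM
  that absorbed the HRF.
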