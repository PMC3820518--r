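---
title: "Modelling the mismatch negativity with hierarchical predictive coding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the mismatch negativity with hierarchical predictive coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mmnsim` simulates the auditory mismatch negativity (MMN) as the scalp
signature of precision-weighted prediction errors in a cortical hierarchy
performing Bayesian inference on its sensory input. This vignette explains
the model, the choices behind every tunable constant, the numerics, and what
the simulations can and cannot say about real data.

## The generative model of a tone

A single tone is described by a three-level hierarchical dynamic model
(HDM). The top level supplies two hidden causes: the loudness cause
`v_l(t)`, a Gaussian bump in native simulation time, and the target
log-frequency `v_nu`, constant over the trial. The middle level holds three
hidden states. The loudness pair `(x_l, x_l')` obeys a driven damped
oscillator

    d(x_l, x_l')/dt = [[0, 1], [-omega^2, -2 zeta omega]] (x_l, x_l')^T
                      + (0, omega^2)^T v_l,

whose eigenvalues are a stable complex pair, so undriven loudness spirals
back to silence. The instantaneous log-frequency relaxes towards its target
at rate `kappa`: `dx_nu/dt = kappa (v_nu - x_nu)` — the picture of an agent
correcting its produced frequency towards an intended one. The bottom level
reads the states out through 50 tonotopic channels with Gaussian tuning of
width `sigma_tune` in log-frequency, multiplicatively scaled by the loudness
read-out `l(x) = x_l`. All stochastic perturbations are smooth: each noise
stream has a Gaussian autocorrelation of width `smoothness`.

The loudness read-out is isolated in one internal function so that
alternative nonnegative read-outs (softplus, exponential) are one-line
swaps; the linear read-out is the simplest choice consistent with a
loudness-modulated spectrogram, and the stimulus envelope is constructed
nonnegative.

## Parameters, defaults and rationale

All constants live in `mmn_config()` and round-trip through YAML
(`write_mmn_config()` / `read_mmn_config()`). Native time is dimensionless;
one unit per integration step, 256 steps per trial.

| parameter | default | why |
|---|---|---|
| `grid$n_steps`, `dt` | 256, 1 | covers pre-stimulus baseline, stimulus, and post-stimulus decay with >= 30 samples per envelope SD |
| `tuning$sigma_tune` | 0.1 log-units | a 32% deviant (0.28 log-units) moves the spectral peak by ~17 of 50 channels without leaving the bank |
| `tuning$span_widths` | 4 | preferred frequencies span +/- 4 tuning widths around the standard |
| `dynamics$kappa_freq` | 0.5 | the instantaneous frequency reaches 95% of a step target within ~6 units, well inside a third of the stimulus duration |
| `dynamics$omega`, `zeta` | 0.25, 0.5 | stable spiral; the impulse response decays below 1% of its peak within ~48 units, fast enough to track the envelope |
| `envelope` | peak 96, SD 28, amplitude 1 | after the time warp the envelope peaks roughly 70 ms after onset with SD near 30 ms |
| `priors$pi_floor`, `pi_scale` | 0.5, 1.5 | precision `pi_floor + pi_scale(-log p)`: continuous, strictly decreasing in p, unbounded as p -> 0, floor as p -> 1 |
| `priors$cause_loudness_logprec` | 2 | moderate confidence in stimulus timing |
| `recognition$obs_logprec` | 2 | sensory evidence accumulates gradually over the tone rather than pinning beliefs instantly, while still dominating the prior at peak loudness (inference within 5% of the standard-deviant spacing at every simulated magnitude) |
| `recognition$state_logprec` | 7 | epistemic confidence in the dynamics; together with `kappa` this sets the evidence-versus-prior balance at the cause level |
| `generation$*_logprec` | 16 | "low noise" stimulus generation, far more precise than recognition |
| `generation$sigma_draw` | 0.005 | trial-to-trial jitter of the target, 5% of a tuning width; standard and deviant distributions stay separated even at 2% deviance |
| `smoothness` | 2 | one noise-smoothness concept shared by generation and recognition |
| `embedding$order_states/causes` | 4 / 2 | standard working range for generalized filtering; higher orders add cost without changing qualitative behaviour |

The generation-side precisions, envelope and grid are the *study
conditions*: the synthetic stimuli the package studies are near-noiseless
realizations of the HDM, with the trial's tone drawn from a narrow normal
centred on the standard (standards) or the standard raised by the deviance
magnitude (deviants).

## Recognition: generalized filtering

Perception is simulated by integrating

    mu_dot = D mu - dE/dmu,   E = 1/2 eps^T Pi_gen eps,

in generalized coordinates of motion (`D` is the block-shift operator).
Three error streams enter `E`: sensory errors `y - g(mu)` (assigned to
primary auditory cortex), state-motion errors `D mu_x - f(mu)` (lateral
Heschl's gyrus) and cause errors `mu_v - eta` (inferior frontal gyrus).
Generalized precisions have Kronecker structure: the inverse covariance of
derivatives of a process with Gaussian autocorrelation, crossed with the
per-component precision. Sensory samples are lifted to generalized
coordinates by a local polynomial (Taylor) fit over a centred window, exact
for polynomials up to the embedding order and clamped at the trial edges.

Numerics:

- **Integrator.** Each step uses local linearization,
  `delta mu = (expm(J dt) - I) J^{-1} h`, with `J` the Gauss-Newton
  Jacobian of the update; gradient flows at the large precisions implied by
  low deviant probability are stiff, and naive Euler destabilizes. If the
  linear solve fails the step falls back to 32 explicit Euler substeps.
- **Divergence guard.** Beliefs exceeding a documented norm bound (1e8)
  raise an error carrying the offending time.
- **Generalized predictions** are nonlinear at order zero and linearized
  (through the Jacobians of `f` and `g`) at higher orders; curvature terms
  are dropped from the update Jacobian, the standard Gauss-Newton
  approximation.
- **Conditional covariances are not propagated**: only posterior
  expectations and precision-weighted errors are exposed, because only the
  errors feed the ERP model.

In the static linear-Gaussian limit the filter's fixed point equals the
conjugate-Gaussian posterior mean exactly (the test suite checks 1e-6
relative agreement), which anchors the scheme against an analytic oracle.

## From prediction errors to the scalp

The time warp is affine: peristimulus zero is stimulus onset at the ear,
scalp time adds a conduction delay (default 10 ms, config-overridable), and
the scale maps the native stimulus duration onto 70 ms. Stimulus duration
is read as the loudness envelope's full width at half maximum — the only
reading that simultaneously yields a ~70 ms duration and a warped envelope
SD near 30 ms; the conduction delay trades off exactly against latency, so
it is reported alongside all latency outputs.

Each precision-weighted error unit passes through a unit-amplitude logistic
`s(lambda xi)` (firing is nonnegative and saturates); units are summed
within a source *after* the sigmoid — each error unit is a neuronal
population generating its own field, and the scalp sees their linear
superposition. The amplitude degeneracy between sigmoid amplitude and lead
field is resolved by fixing the sigmoid amplitude at 1. The scalp potential
is `sum_i w_i LFP_i + offset`, baseline-corrected over the pre-stimulus
interval; simulated data processing resamples to 200 Hz and applies a
single-pass 3rd-order Butterworth low-pass at 40 Hz (the filter is primed
with the first sample so DC passes with unit gain). Latency estimation uses
the unfiltered wave, amplitude the filtered one.

Because the empirical recordings the original observation parameters were
fitted to are not available, the default slopes `(1, 0.2, 3)` and lead
field `(-2, -0.5, -2)` µV are package choices, set so that (i) the MMN is a
negativity of a few µV at large deviance, (ii) the IFG stream operates in
the saturating regime of its sigmoid while the A1 stream stays nearly
linear, and (iii) the four qualitative phenomenological patterns emerge.
The mechanism is the one the model itself suggests: sustained
frequency-cause errors (IFG) deepen the trough uniformly and carry the
probability effect multiplicatively, while the early transient sensory
error (A1) grows superlinearly with deviance magnitude, so at large
magnitudes an early trough component emerges and the fractional-area
latency shortens — and saturation of the sustained stream amplifies exactly
this dissociation.

## MMN estimators

The MMN is the deviant-minus-standard difference wave. Latency is the 50%
fractional-area point: the trough minimum defines a half-depth threshold
("half the MMN amplitude" is read as half the most negative value — the
only self-contained definition available before the amplitude estimator
runs); the window runs from the first to the last half-depth crossing
(linearly interpolated); the rectified-negative area inside the window is
accumulated by trapezoids and the latency interpolates the half-area point
sub-sample-accurately. A wave with no negative deflection returns `NA`
flagged "no MMN detected". Amplitude is the mean filtered voltage within
±10 ms of the latency; a window truncated by the trial edge is an error.

## Experiment orchestration

`run_condition()` reproduces the two-simulation protocol behind one MMN
estimate: the same physical tone B is filtered by an expected-A listener
(deviant ERP) and an expected-B listener (standard ERP), with one prior
precision per condition. Both runs share the stimulus realization, so the
difference wave isolates the effect of expectation; at zero deviance
magnitude the two listeners coincide and the MMN is exactly null.
`mmn_sweep()` crosses deviance magnitudes (2, 4, 12.7, 27, 32%) with
deviant probabilities (0.05–0.4); rows that differ only in probability
reuse the same stimulus, because probability manipulates the prior alone —
this isolates the manipulated variable exactly as comparing "responses to a
deviant under different degrees of prior certainty" requires. Failures are
recorded per row and the sweep continues.

## Fitting the observation model

`fit_observation_params()` estimates the sigmoid slopes and lead field by
multi-start bounded Levenberg–Marquardt least squares against a standard
and deviant target waveform jointly (at least 20 seeded starts by default;
slopes bounded in [1e-3, 1e3], lead field in [-100, 100] µV, keeping the
logistic away from pure-saturation plateaus with vanishing gradients). The
constant offset is annihilated by baseline correction and therefore
structurally unidentifiable: it is held fixed, not estimated. Because
slopes and lead-field weights trade off in the near-linear regime, the fit
reports the identifiable gains `w_i lambda_i / 4` and the condition number
of the local Gauss–Newton Hessian as a degeneracy flag. Validation is by
parameter recovery on targets generated by the package's own forward model.

## Problem sizes

Trials are 256 steps of native time; the default sweep is 25 conditions
(each two filtering runs); recovery fits use 20 starts on two ~55-sample
200 Hz targets; Monte-Carlo noise checks use 1000 realizations. These sizes
resolve the envelope and give stable contrasts while keeping a full run of
the suite and the acceptance script in the minutes range on one CPU.

## What the synthetic data do and do not show

The generator emulates single standard/deviant trials of a frequency
oddball with a loudness-bump tone, smooth low-amplitude noise, and a
listener whose internal model matches the generator except for its prior
on the target frequency. It does not emulate: multi-tone sequences or
trial-to-trial learning (precisions are set per condition, not learned),
cochlear or subcortical transduction, volume-conductor head models or
multi-electrode topographies, overlapping ERP components unrelated to
prediction error, or realistic measurement noise. Passing tests therefore
show that the inference-to-ERP pipeline produces the qualitative MMN
phenomenology under its own assumptions — not that these parameters fit any
particular empirical dataset. Latencies live on the package's peristimulus
axis and are directly comparable only within it.

## Known limitations

- The latency transition with deviance magnitude is sharp (bimodal between
  a sustained-trough regime and an early-transient regime) rather than
  gradual.
- Equal-spaced tonotopic channels make the spectral argmax of tones landing
  midway between two preferred frequencies sensitive to floating-point
  ties.
- The mapping from deviant probability to prior precision is a documented
  monotone default, not a learned quantity.
- Single-pass causal filtering delays the filtered wave by a few
  milliseconds at low frequencies relative to the unfiltered wave used for
  latency estimation; both conventions are kept deliberately (latency on
  unfiltered, amplitude on filtered).
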