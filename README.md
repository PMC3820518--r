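# mmnsim: predictive-coding simulation of the auditory mismatch negativity

The mismatch negativity (MMN) is the negative deflection of the
event-related potential (ERP) evoked by a rare *deviant* tone embedded in a
stream of repeated *standard* tones, conventionally estimated as the
deviant-minus-standard difference wave. Its amplitude grows with the
proportional frequency difference between deviant and standard (*deviance
magnitude*) and with the rarity of deviants (*deviant probability*), while
its latency shortens with magnitude but is largely insensitive to
probability.

`mmnsim` is for computational neuroscientists who want to simulate this
phenomenology from first principles. It models auditory cortex as inverting
a three-level hierarchical dynamic model (HDM) of tone generation by online
Bayesian inference, and models the scalp ERP as the superposition of fields
generated by neurons encoding precision-weighted prediction errors.

## The model

**Generative model.** A tone is generated by hidden causes
*v = (v_l, v_nu)* — a loudness envelope (Gaussian bump in time) and a
constant target log-frequency — driving hidden states
*x = (x_l, x_l', x_nu)*:

- loudness pair: a damped oscillator `d(x_l, x_l')/dt = A (x_l, x_l')ᵀ + b v_l`
  with a stable complex eigenpair (decaying spiral),
- instantaneous log-frequency: `dx_nu/dt = kappa (v_nu − x_nu)`,
- observation: 50 tonotopic channels with Gaussian tuning in log-frequency,
  `y_i = x_l · exp(−(x_nu − nu_i)² / 2σ²) + noise`; all noises are smooth
  (Gaussian autocorrelation).

**Recognition.** Perception is simulated by generalized filtering —
gradient descent on precision-weighted prediction error in generalized
coordinates of motion (value, velocity, acceleration, ...):

```
mu_dot = D mu − dE/dmu,   E = ½ εᵀ Π ε,   ξ = Π ε
```

with sensory errors (primary auditory cortex, A1), state-motion errors
(lateral Heschl's gyrus) and cause errors (inferior frontal gyrus, IFG).
The listener's expectation enters as a Gaussian prior on the target
log-frequency: its mean is the expected tone and its precision is mapped
from the deviant probability (`pi_floor + pi_scale · (−log p)` — rarer
deviants, more confident predictions).

**Forward model.** The three error streams are warped to peristimulus
milliseconds (native stimulus duration → 70 ms, plus a conduction delay),
passed per unit through a logistic activation `s(λ ξ)`, summed within each
source, and combined as `v(t) = Σ w_i LFP_i(t) + offset`, then downsampled
to 200 Hz and low-pass filtered (3rd-order Butterworth, 40 Hz). The MMN
difference wave is summarized by its fractional-area (50%) latency on the
unfiltered wave and the mean voltage of the filtered wave within ±10 ms of
that latency.

## Worked example

```r
library(mmnsim)

cnd <- oddball_condition(standard_hz = 1000, deviance_magnitude = 0.127,
                         deviant_probability = 0.05)
run <- run_condition(cnd, rng_seed = 42)
print(run)
#> Oddball condition: 1000 Hz standard, +12.7% deviant, p = 0.05
#>   MMN latency 83.4 ms (fractional area, + 10 ms conduction shift included)
#>   MMN amplitude -0.652 uV (windowed mean), peak -0.715 uV
```

The run simulates the pair of experiments behind one MMN estimate: the same
1270 Hz tone is presented to a listener expecting the 1000 Hz standard
(deviant ERP) and to a listener expecting 1270 Hz (standard ERP); both
listeners hold their beliefs with the precision implied by p = 0.05. The
difference wave troughs at −0.72 µV; its area-median latency is 83 ms on
the package's peristimulus axis (which includes the documented 10 ms
conduction delay — latencies are only interpretable relative to it).
`plot(run)` overlays the two ERPs and the MMN; `run$mmn_filtered` is the
difference wave.

A full deviance-magnitude × deviant-probability experiment:

```r
tbl <- mmn_sweep(seeds = 1)          # 5 magnitudes x 5 probabilities
attr(tbl, "contrasts")               # the four qualitative MMN patterns
```

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts/mmn_cli.R", package="mmnsim"))') \
    simulate --magnitude 0.32 --probability 0.05 --seed 4 --out-dir out
```

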