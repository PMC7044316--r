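# beatattn

Tools for studying **periodic temporal attention** — the ability to focus
attention at the moments an isochronous stream makes relevant. The package
implements the complete computational chain of a beat-discrimination study:
stimulus sequence generation with validated structural constraints, a
synthetic observer for end-to-end validation, the behavioural estimators
(optimal-tempo cubic fits, tapping precision/variability, sensorimotor
simultaneity, AIC Bayes factors), a stochastic three-oscillator model of
stimulus–attention–motor coupling, and a seeded pipeline tying them together.

Intended audience: researchers in auditory/visual psychophysics and
computational neuroscience who want to simulate, analyse or model
beat-based attention experiments with reproducible, unit-tested code.

## The model

Three phase oscillators — stimulus *S*, attention *A*, motor *M* — are
coupled with transmission delays and driven by white noise:

```
dθ_S/dt = ω_S
dθ_A/dt = ω_A + K_AM sin(θ_M(t−τ_AM) − θ_A) + K_AS sin(θ_S(t−τ_AS) − θ_A) + ξ_A
dθ_M/dt = ω_M + K_MA sin(θ_A(t−τ_MA) − θ_M) + K_MS sin(θ_S(t−τ_MS) − θ_M) + ξ_M
```

with `<ξ_i(t) ξ_j(t')> = 2 D_i δ(t−t') δ_ij`. Attentional performance is
proxied by the stimulus–attention phase-locking value
`PLV = |mean(exp(i(θ_S − θ_A)))|`. Sweeping the stimulus frequency produces
an inverse-U locking curve whose peak sits near the attentional natural
frequency (≈1.5 Hz auditory, ≈0.7 Hz visual), and the sign of the effect of
strengthening the motor-to-attention coupling flips with the stimulus–motor
delay — beneficial at 0.1 s (auditory), detrimental at 0.35 s (visual).
Integration is Euler–Maruyama in C++ (via Rcpp) at dt = 25 ms with
delay buffers and a burn-in discard.

## Worked example

```r
library(beatattn)

# 1. Generate one validated trial: references, on-beat targets,
#    off-beat distractors, final deviant.
tr <- generate_trial(beat_spec(1.3), density = 1, deviant_on_beat = FALSE,
                     modality = "auditory", seed = 42)
print(tr)
#> <trial_sequence> 1.3 Hz auditory, 11 events (4 targets, 3 distractors), deviant off-beat (+0.336 s)

# 2. Simulate a full synthetic experiment (8 tempi x 40 trials x 2 sessions)
#    and estimate the behavioural optimal tempo.
ds <- generate_experiment("auditory_8", n_trials_per_condition = 40,
                          params = observer_params(modality = "auditory"),
                          density = 1, sessions = c("passive", "tracking"),
                          seed = 7)
pc <- performance_curve(ds$trials[ds$trials$session == "passive", ])
print(pc, digits = 3)
#>   condition_hz prop_correct  n
#> 1          0.6        0.550 40
#> 2          0.7        0.650 40
#> 3          1.0        0.775 40
#> 4          1.3        0.725 40
#> 5          1.7        0.625 40
#> 6          2.2        0.625 40
#> 7          2.9        0.525 40
#> 8          3.8        0.600 40
fit <- fit_cubic_optimal_tempo(pc$condition_hz, pc$prop_correct)
fit$alpha       # 1.302  (Hz; estimated accuracy maximum)
fit$r_squared   # 0.726

# 3. Tapping metrics for one tracking trial at 1.7 Hz.
rec <- Filter(function(r) abs(r$period - 1/1.7) < 1e-9, ds$tap_records)[[1]]
tapping_precision(rec)                            # 100.2  (% of the beat rate)
tapping_cv(rec)                                   # 0.0696
mean(sensorimotor_simultaneity(rec)$phi_signed)   # -0.327 rad (anticipatory)

# 4. Sweep the oscillator model over the same tempo axis.
sw <- frequency_sweep(preset("auditory", "passive", duration = 1000),
                      c(0.3, 0.4, 0.6, 0.7, 1, 1.3, 1.7, 2.2, 2.9, 3.8),
                      n_realizations = 10, base_seed = 1)
print(as.data.frame(sw), digits = 3)
#>    stim_freq_hz plv_mean  plv_sd  n
#> 1           0.3    0.513 0.01058 10
#> 2           0.4    0.536 0.00855 10
#> 3           0.6    0.581 0.00857 10
#> 4           0.7    0.595 0.00660 10
#> 5           1.0    0.647 0.00236 10
#> 6           1.3    0.677 0.00727 10
#> 7           1.7    0.679 0.00605 10
#> 8           2.2    0.625 0.00661 10
#> 9           2.9    0.474 0.00711 10
#> 10          3.8    0.323 0.00557 10
mf <- fit_cubic_optimal_tempo(sw$stim_freq_hz, sw$plv_mean)
mf$alpha   # 1.4086  (model PLV peak, Hz)

# 5. How well does the model locking curve track this one synthetic
#    behavioural replicate?
fit_to_behavior(sw[sw$stim_freq_hz %in% pc$condition_hz, ], pc)$r_squared
#> 0.280   (a single 40-trial replicate is noisy; the expected-accuracy
#>          curve correlates far more strongly)
```

Both curves peak in the same place — behavioural optimum 1.30 Hz, model PLV
peak 1.41 Hz — which is the package's central phenomenon: a
modality-specific preferred tempo emerging from coupled-oscillator dynamics.

A one-shot orchestration of all stages (paradigm → observer → metrics →
model) is available via `run_config()` / `run_all()`, which write tidy CSVs
plus a `report.json` with file digests; see `?run_all`. A thin command-line
front end lives at `inst/cli/beatattn.R`.

## Documentation

The methods vignette (`vignettes/periodic-temporal-attention.Rmd`) documents
the model equations and units, every tunable parameter with its default and
rationale, what the synthetic observer does and does not emulate, the
numerical choices in the integrator and estimators, and known limitations.
All exported functions have reference documentation (`?beatattn`).
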