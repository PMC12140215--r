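# entrainkit

Estimators and simulation tools for studying how rhythmic stimulation
entrains behavior and brain activity. The target setting is auditory
psychophysics: listeners detect brief silent gaps in noise while a rhythm
is imposed either acoustically (a frequency-modulated, FM, carrier) or
electrically (transcranial alternating current stimulation, tACS), and the
question is whether detection performance — and the EEG — locks to the
rhythm's phase, at which lag, and at which frequency for which individual.

The package is written for researchers analyzing phase-binned detection
data: it provides the estimators, their permutation-based inference, the
oscillator model used to interpret individual differences, and a seeded
synthetic-data generator that reproduces the three experimental designs the
pipeline targets, so every stage can be validated on data with known ground
truth.

## What it computes

**Behavioral entrainment.** Gaps are binned by the phase φ of the relevant
rhythm at gap onset; hit rates per bin are fit with a single-cycle cosine

    rate(φ) = offset + A · cos(φ − φ₀),

via the linear sin/cos basis. The amplitude A ≥ 0 (*entAmp*) quantifies
entrainment strength and φ₀ is the preferred phase (*prefPhase*).
Significance comes from surrogate nulls that shuffle single-trial accuracy
while keeping phase labels fixed (`surrogate_null`, `zscore_vs_null`,
`exceeds_null`); circular uniformity of preferred phases is tested with
`rayleigh_test`.

**tACS lag analysis (concurrent FM + tACS).** A 9 (FM phase) × 6 (FM–tACS
lag) binning, first-level cosine fits per lag, a second-level fit giving
the individually optimal lag, realignment to that lag with exclusion of the
realigned peak and trough bins, and half-cycle contrasts tACS(+) − tACS(−)
z-scored against lag-shuffle surrogates that rerun the whole pipeline
(`profile_entrainment_by_lag`, `second_level_fit`, `realign_profile`,
`half_cycle_summary`, `tacs_effect_zscores`, `extract_tacs_phase`).

**tACS without auditory rhythm.** Entrainment to tACS phase per stimulation
frequency, referenced to an "imaginary oscillator" baseline that resets at
stimulus onset in sham, with the normalized effect
(entAmp-tACS − baseline)/baseline and a responder criterion of > 1
(`baseline_oscillator_phase`, `baseline_amplitude`, `normalized_effect`,
`exp2_summary`).

**Oscillator model.** A Stuart–Landau limit-cycle oscillator

    dx/dt = λx − ωy − γ(x² + y²)x + k·s(t)
    dy/dt = λy + ωx − γ(x² + y²)y

with λ = 0.2, γ = 1.0, driven by a sine at the tACS frequency with strength
k relative to the baseline amplitude √(λ/γ) ≈ 0.45. A grid sweep over
ω (0.1–8 Hz) and k (0–1) yields entrainment-change profiles whose
correlation with a participant's empirical tACS-effect profile estimates
the individual resonance frequency; estimates are grouped by average-linkage
clustering (`integrate_oscillator`, `entrainment_change`,
`sweep_oscillator`, `estimate_resonance`, `cluster_resonances`).

**EEG frequency tagging.** Hann-windowed amplitude spectra of trial
averages, intertrial phase coherence (resultant vector length),
fronto-central cluster averaging, cross-condition normalization, preferred
rates and linear trends across stimulation rates (`evoked_spectrum`,
`itc_spectrum`, `cluster_average`, `normalize_across_conditions`,
`preferred_rate`, `linear_trend`).

**Trial-wise models.** Mixed-effects logistic regressions of single-gap
accuracy with circularly linearized phases, AIC model selection, and
surrogate-AUC significance (`build_design`, `fit_candidates`,
`surrogate_auc`).

## Worked example

```r
library(entrainkit)

# Simulate one Experiment-1-style participant (2-Hz FM sound + 2-Hz tACS)
cfg <- design_config("exp1", n_participants = 1, conditions = "39", seed = 11)
trials <- simulate_outcomes(gen_design(cfg),
                            behavioral_params(fm_pref_phase = 1.0,
                                              lag_opt = 0.5),
                            seed = 12)
nrow(trials)
#> [1] 638

# Behavioral entrainment to the FM stimulus (sham trials)
sham <- trials[trials$stim == "sham", ]
bins <- phase_binning(9)
fit <- entrainment_fit(sham, bins, "fm_phase")
fit
#> cosine fit: offset 0.5866, amplitude 0.1352, phase 0.080 rad

# Is the modulation stronger than chance? Permutation surrogate null
null <- surrogate_null(sham, bins, "fm_phase", n_perm = 1000, seed = 13)
zscore_vs_null(fit$amplitude, null)
#> [1] 0.6038458
exceeds_null(fit$amplitude, null)
#> [1] FALSE

# Full tACS lag analysis: optimal lag, realigned half-cycle contrasts
eff <- tacs_effect_zscores(trials, n_perm = 1000, seed = 14)
eff
#> tACS effect: tACS(+) 0.2049, tACS(-) 0.1362, sham 0.1352
#>   z: +vs sham 1.14, - vs sham 0.65, + vs - 0.41 (1000 surrogates)

# Oscillator model: entrainment change when drive matches the oscillator
entrainment_change(oscillator_params(omega = 2, k = 0.5, drive_freq = 2))
#> [1] 37.97978
```

Reading the output: this participant's sham-condition hit rate is modulated
by FM phase with amplitude 0.135 around a 0.587 baseline, but with only
~90 sham gaps that amplitude does not exceed the 95th percentile of its
surrogate null (z = 0.60) — single-participant significance needs a strong
modulation at this trial count. The lag analysis estimates the optimal
tACS lag, realigns the lag profile, and reports the half-cycle amplitudes:
entrainment is numerically larger in the optimal half-cycle (0.205 vs
0.136), with z-scores quantifying each contrast against lag-shuffled
surrogates. The last line is the model side: a drive at the oscillator's
own frequency with half-baseline strength grows the oscillation amplitude
by ~38%, while strongly detuned drives leave it essentially unchanged —
the Arnold-tongue logic behind the resonance-frequency estimator.

A methods vignette (`vignettes/methods.Rmd`) documents the model choices,
parameter defaults, numerical decisions and the limits of what the
synthetic-data validation shows.

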