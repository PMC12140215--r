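---
title: "Quantifying entrainment to rhythmic auditory and electrical stimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying entrainment to rhythmic auditory and electrical stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrainkit)
```

## The scientific problem

When a listener detects brief silent gaps embedded in an ongoing sound,
performance is not constant in time: it waxes and wanes with the phase of a
rhythmic stimulus. Two kinds of rhythm can impose such structure — the
acoustic one (a frequency-modulated, FM, carrier whose modulation cycle
defines moments of better and worse detectability) and an electrical one
(transcranial alternating current stimulation, tACS, intended to entrain the
underlying neural oscillation). `entrainkit` implements the estimators
needed to quantify both kinds of behavioral entrainment, the two-level
analysis of their interaction, an oscillator model that explains individual
differences in tACS efficacy by a latent resonance frequency, and the EEG
frequency-tagging measures of neural entrainment. A seeded synthetic-data
generator reproduces the three experimental designs end to end, so every
estimator can be validated against data whose ground truth is known.

## The core estimator: phase-binned cosine fits

Each gap is tagged with the phase of the relevant rhythm at its onset
(FM phase, tACS phase, or the phase of a hypothetical oscillator). Phases
live in radians on `[-pi, pi)`; `phase_binning(n)` partitions the circle
into `n` half-open, equally spaced bins with one bin centered exactly at
phase zero (centers `2*pi*j/n`, wrapped). Hit rates per bin are fit with a
single-cycle cosine,

$$\mathrm{rate}(\varphi) = \mathrm{offset} + A\cos(\varphi - \varphi_0),$$

via the linear sine/cosine basis, which shares its optimum with the
nonlinear amplitude/phase parameterization. The amplitude $A \ge 0$ (called
*entAmp* in this literature) measures entrainment strength; $\varphi_0$ is
the preferred phase. On equally spaced bins the basis is orthogonal, so
noiseless cosine data are recovered to machine precision (the test suite
checks this against a dense two-dimensional grid search).

Because $A$ is a norm of two regression coefficients it is positively
biased in small samples: even flat data give $A > 0$. Every inferential use
therefore compares the observed amplitude to a permutation null
(`surrogate_null`): accuracy values are shuffled across a participant's
trials while phase labels stay fixed (1,000 surrogates by default), and a
participant counts as significantly entrained when the observed amplitude
exceeds the null's 95th percentile. z-scores against the null mean/SD put
amplitudes from different conditions on a common scale. The suite verifies
that the test's type-I error at the 95th percentile stays in a
[0.025, 0.08] band over 500 simulated null participants.

## The tACS phase-lag analysis

With concurrent FM sound and tACS at the same frequency, the question is
whether the FM-phase entrainment amplitude depends on the lag between the
two rhythms. Gaps are binned 9 (FM phase) by 6 (FM–tACS lag); a first-level
cosine fit per lag bin yields an amplitude profile over lag; a second-level
cosine fit to that profile gives the individually optimal lag. Profiles are
then realigned so the bin nearest the optimal lag sits at zero (ties go to
the lower bin index, for determinism).

Realignment selects the empirical peak, which inflates the zero bin by
construction. The pipeline therefore excludes the realigned zero bin and
its opposite, and summarizes the optimal half-cycle as the mean of the two
bins adjacent to zero (*tACS(+)*) versus the two adjacent to $\pi$
(*tACS(−)*). Contrasts (each versus the sham amplitude, and against each
other) are z-scored against surrogates that shuffle the lag labels and
rerun the *entire* pipeline — binning, both fits, realignment, exclusion —
per permutation, because the selection step must be inside the null.
Observed data must fill all 54 cells (participants with empty cells are
excluded); a lag shuffle that empties a cell by chance — expected in a
fraction of a percent of permutations at ~11 trials per cell — fits that
lag bin on its remaining FM bins rather than discarding the permutation,
which would otherwise bias the null toward balanced shuffles. The
acceptance suite confirms the point of the exclusion: on lag-independent
data the mean z of the plus-minus contrast stays within ±0.1 of zero across
500 simulated participants.

One modeling choice is open in this design: when the second-level fit is
asymmetric, "adjacent to the trough" could mean adjacent to the fitted
trough instead of to the bin opposite the realigned zero. We use adjacency
to the realigned $\pi$ bin, which keeps the two half-cycles structurally
symmetric and the exclusion unbiased.

Raw stimulation recordings can be converted to instantaneous phase with
`extract_tacs_phase`: a fourth-order zero-phase Butterworth band-pass
(1–10 Hz — only the band is prescribed by the design; the order is ours)
followed by the analytic-signal angle, so a cosine has phase zero at its
peaks.

## Experiment-2 logic: baselines and normalized effects

With unmodulated noise stimuli, entrainment to tACS phase is estimated per
stimulation frequency (6 phase bins). Its natural reference is the
*imaginary baseline oscillator*: a hypothetical oscillation that resets to
phase zero at stimulus onset, whose phase at a gap is `wrap(2*pi*f*t)`.
Fitting the same cosine to sham trials binned by this phase yields a
baseline amplitude per frequency that carries exactly the same small-sample
bias as the tACS estimate — which is why the normalized effect
`(entAmp_tACS - baseline)/baseline` is approximately centered under the
null even though both ingredients are positively biased. A normalized
effect above 1 (tACS amplitude at least twice baseline) flags a responder
at that frequency. Baselines below `1e-3` trigger an "unstable
normalization" warning rather than a silent division; near-zero baselines
make the ratio explode and should be treated as missing in group analyses.

## The Stuart–Landau oscillator model

Individual variability in the effective tACS frequency is interpreted with
a canonical limit-cycle model of two coupled neural populations:

$$\dot x = \lambda x - \omega y - \gamma(x^2+y^2)x + k\,s(t), \qquad
  \dot y = \lambda y + \omega x - \gamma(x^2+y^2)y,$$

with $\lambda = 0.2$, $\gamma = 1.0$, initial state $(0, -1)$, and
$s(t)$ a zero-phase sine at the drive frequency switched on at 10 s.
$\omega$ is exposed in Hz and converted to angular frequency internally.
The undriven limit cycle has amplitude $\sqrt{\lambda/\gamma} \approx
0.447$; the drive strength `k` is expressed as a fraction of that
amplitude, so the additive coefficient is `k * sqrt(lambda/gamma)`.
Integration uses an adaptive Dormand–Prince 4/5 scheme (relative tolerance
$10^{-6}$) with a compiled right-hand side; the suite checks that halving
the tolerance moves the post-transient amplitude by less than $10^{-4}$.

The effect of the drive is summarized as the percent change of the
oscillation amplitude, measured as the mean envelope $\sqrt{x^2+y^2}$ over
a post-transient analysis window (15–30 s, i.e. 5 s after drive onset to
the end). The baseline is the same quantity from a matched undriven run
over the same window. Using matched runs rather than the pre-onset segment
matters numerically: the prescribed initial state lies off the limit cycle
and its relaxation transient is still ~2% large during 5–10 s, which would
otherwise leak into the baseline; with matched windows the change is
identically zero for `k = 0`. The analysis window always contains an
integer number of drive cycles for the four drive frequencies used.

`sweep_oscillator` fills the published grid — $\omega$ from 0.1 to 8 Hz in
0.1-Hz steps, `k` from 0 to 1 in steps of 0.1, drives at 0.8, 2, 3.2 and
4.4 Hz (3,520 cells, about 10 s of wall time with the compiled
right-hand side; the result is deterministic and cacheable). At these
drive strengths the entrainment region is narrow: only the grid point
matching the drive frequency shows a large positive change (~38% at
`k = 0.5`), while a 0.2-Hz detuning already produces beating and a small
negative change. This is the Arnold-tongue structure the resonance
estimator exploits.

`estimate_resonance` Pearson-correlates a participant's 4-point normalized
tACS-effect profile with the model profile at every $(\omega, k)$ cell and
reports the $\omega$ of the global maximum (ties toward lower $\omega$,
then lower `k`; maximization is joint over both parameters). Correlation
is invariant to positive affine transforms of the profile, so the
empirical measure's units do not matter. On noiseless model-generated
profiles the estimator returns the generating $\omega$ for every grid
point whose correlation maximum is unique. With Gaussian noise at 10% of
the profile range, recovery within ±0.5 Hz holds in ~88% of draws when the
generating $\omega$ lies in 0.8–4.4 Hz — the range actually probed by the
drive frequencies, and the range the synthetic generator draws latent
resonance frequencies from (log-uniformly). Outside that range the
4-point profile is nearly flat and carries little shape information, so
recovery degrades; with only four probe frequencies this is an
identifiability limit of the design, not of the estimator. Estimated
resonance frequencies are grouped with average-linkage hierarchical
clustering on Euclidean distances (`cluster_resonances`).

## EEG frequency tagging

Neural entrainment is read from two spectra. The evoked amplitude spectrum
(`evoked_spectrum`) transforms the Hann-windowed trial average; phase-random
activity cancels in the average, so the spectrum isolates phase-locked
components. The periodic Hann window is used and amplitudes are scaled by
`2/sum(w)`, so a unit-amplitude on-bin sinusoid reads exactly 1. Intertrial
phase coherence (`itc_spectrum`) applies the same windowed transform per
trial and takes the resultant vector length of the per-trial phase phasors:
1 for perfect phase locking, about $\sqrt{\pi}/(2\sqrt{n})$ for random
phases. The window is reused per trial for consistency between the two
measures.

Epoch parameters default to 10 s at 500 Hz, so all four stimulation rates
fall exactly on 0.1-Hz Fourier bins and no leakage ambiguity arises; the
test fixtures use 100 Hz (still far above twice the highest 4.4-Hz target)
to keep arrays small. Off-bin targets are read at the nearest bin with a
warning. Channel values are averaged over the standard fronto-central
cluster (F3, Fz, F4, FC1, FCz, FC2, C3, Cz, C4), the typical auditory
topography.

To compare rates despite frequency-dependent noise floors (1/f noise,
per-bin estimation noise), responses are normalized across conditions: the
value at frequency `f` in the matching condition is divided by the mean
value at `f` across the non-matching conditions. The preferred rate is the
argmax of the normalized vector length (ties to the lower rate, flagged),
and the effect of rate is assessed with an ordinary linear model of the
normalized measures on rate.

## The synthetic-data generator

The generator is first-class, tested code: it encodes the study conditions
the estimators are validated under.

* **Designs.** Experiment 1: 27 participants, two modulation-depth sessions
  (11%, 39%), 5 blocks of 32 twenty-second stimuli with 3–5 gaps each
  (~136 gaps per block), gaps at the centers of 9 FM-phase bins (balanced
  within participant and condition to within one trial), at least 1.5 s
  apart and at least 1 s from the stimulus edges; one of seven interleaved
  stimulation conditions is sham. Experiment 2: 24 participants, one block
  per condition (sham and tACS at 0.8/2/3.2/4.4 Hz). Experiment 3: 12
  participants, 4 FM rates, 15 phase bins, 56 stimuli per rate.
* **Hit model.** Additive cosine with clipping:
  `p = clip(base + A * cos(phase - pref), 0.02, 0.98)`. The additive form
  matches the cosine-fit estimand exactly, so recovery tests are exact in
  expectation. Base rate 0.5 reflects the threshold-tracked task. Depth
  amplitudes default to 0.04 (11%) and 0.08 (39%) — small, as expected at
  low modulation depths, and ordered with depth. In Experiment 1 the FM
  amplitude is modulated by tACS lag with gain `tacs_modulation`
  (default 0.5) around a per-participant optimal lag. In Experiment 2 the
  tACS-phase amplitude follows a Gaussian in log-frequency (width 0.6
  octaves) around a latent resonance frequency drawn log-uniformly from
  0.8–4.4 Hz; no tuning law is prescribed by the design, only frequency
  specificity, and a log-frequency Gaussian is the standard neutral choice.
  Sham trials carry a weak intrinsic rhythm (amplitude 0.03) at the
  resonance frequency, phase-locked to stimulus onset, so baselines are
  estimable. In Experiment 3 the FM amplitude increases linearly with rate
  (0.015 per Hz).
* **tACS lags** are drawn uniformly on the circle per trial: lags arise
  from random stimulus start phases, which makes them effectively uniform.
* **Response times** for hits are uniform on 0.2–1.0 s; RT distributions
  are not analyzed beyond means, so no richer model is warranted.
* **Raw press streams** (`simulate_press_stream`) exercise the scorer:
  a press 100–1500 ms after a gap is a hit (first unused press wins; each
  press credits at most one gap); presses outside every response window
  are false alarms. A spontaneous press that happens to fall inside a
  gap's window is indistinguishable from a hit and is scored as one —
  exactly as in the real task.
* **EEG epochs** are a phase-locked cosine at the stimulus rate plus
  `1/f` noise, with per-trial phase jitter controlling coherence.

What the generator does *not* emulate: sequential dependencies and lapses
in behavior, realistic EEG topography and correlated channel noise,
artifacts, and any mismatch between the additive-cosine hit model and real
psychometric nonlinearities. Passing tests therefore certify the
estimators' correctness and calibration under the assumed effect
structure, not the empirical conclusions of any particular dataset.

## Problem sizes and numerical choices

Simulation studies in the test suite use sizes chosen to keep Monte-Carlo
error well inside the asserted bands: 500 null participants for the
permutation-test calibration (binomial SE ~0.01 on a 0.05 rate), 500
participants with 200 lag-shuffle surrogates each for the realignment bias
check (SE of the mean z ~0.045 against a ±0.1 band), 200 noisy draws for
resonance recovery, 100 generator runs for AIC model recovery, and 12
simulated participants (the Experiment-3 sample size) for the EEG trend.
Degenerate inputs fail loudly everywhere: empty phase bins or FM-by-lag
cells name the offending cell (participants with empty cells are excluded,
as in the source designs), zero-variance surrogate distributions refuse to
z-score, flat cosine fits carry a `degenerate` flag, and constant signals
have no defined phase.

## Trial-wise model comparison

`fit_candidates` compares mixed-effects logistic regressions of single-gap
accuracy with a participant random intercept (Laplace approximation, as in
the original analysis; `nAGQ = 0` is available for large simulation
studies). Phases enter as sin/cos pairs; the five default families are
{FM}, {tACS}, {FM × depth}, {tACS × depth} and the full two-interaction
model — the published table of five candidates is summarized rather than
enumerated, so the sets are configurable. The lowest AIC wins; the
winner's significance is assessed by refitting it on outcome permutations
(within participant) and comparing in-sample AUCs of the conditional
predictions (no cross-validation is used, and the AUC is computed with a
fixed comparison direction so the null centers at one half).

## Known limitations

* The cosine fit is unweighted, so bins with fewer trials carry equal
  weight; with balanced designs this is immaterial, but strongly
  unbalanced tables would benefit from weighted fits.
* The resonance estimator's grid search cannot distinguish oscillator
  frequencies outside the probed 0.8–4.4 Hz range (see above).
* In-sample AUC overstates absolute classification performance; it is
  used only relative to its permutation null.
* The oscillator model's entrainment-change metric summarizes the
  envelope; spectrally selective measures would behave differently for
  strongly detuned drives.
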