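Package: entrainkit
Title: Behavioral and Neural Entrainment to Rhythmic Auditory and
    Electrical Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimators and simulation tools for quantifying entrainment of
    gap-detection behavior and EEG activity to rhythmic stimulation.
    Implements phase-binned cosine-fit entrainment amplitudes with
    permutation surrogate nulls, the two-level tACS phase-lag analysis with
    realignment and half-cycle contrasts, imaginary-oscillator baselines and
    normalized tACS effects, a Stuart-Landau oscillator model with grid
    sweeps and correlation-based resonance-frequency estimation, EEG
    frequency-tagging metrics (evoked amplitude spectra and intertrial phase
    coherence), and trial-wise mixed-effects logistic model comparison by
    AIC with surrogate AUC significance. A seeded synthetic-data generator
    reproduces the designs of the three experiments the pipeline targets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    lme4,
    pROC,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
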