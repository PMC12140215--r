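#' Phase of an imaginary baseline oscillator
#'
#' A hypothetical oscillator at frequency `f` that resets to phase zero at
#' stimulus onset; its phase at a gap presented `gap_time` seconds into the
#' stimulus is `wrap(2*pi*f*gap_time)`. Used to estimate baseline rhythmic
#' performance fluctuations from sham trials.
#'
#' @param gap_time Gap onset time (s from stimulus onset), >= 0.
#' @param f Oscillator frequency in Hz (> 0).
#' @return Phase in radians, wrapped to `[-pi, pi)`.
#' @examples
#' baseline_oscillator_phase(0.25, 2)  # pi
#' @export
baseline_oscillator_phase <- function(gap_time, f) {
  if (f <= 0) stop("baseline_oscillator_phase: f must be > 0")
  if (any(gap_time < 0)) stop("baseline_oscillator_phase: negative gap_time")
  wrap_phase(2 * pi * f * gap_time)
}

#' Baseline rhythmic-fluctuation amplitude from sham trials
#'
#' Bins sham-condition gaps by the phase of the imaginary oscillator at
#' frequency `f` and fits a cosine; the amplitude serves as the baseline
#' against which the tACS entrainment amplitude at `f` is normalized.
#'
#' @param sham_table Sham-condition trial table with `gap_time` and
#'   `accuracy`.
#' @param f Oscillator frequency in Hz.
#' @param binning Phase binning (default 6 bins, as for the tACS phase).
#' @return Cosine-fit amplitude (>= 0).
#' @export
baseline_amplitude <- function(sham_table, f, binning = phase_binning(6)) {
  if (nrow(sham_table) == 0) stop("baseline_amplitude: no sham trials")
  tb <- sham_table
  tb$osc_phase <- baseline_oscillator_phase(tb$gap_time, f)
  entrainment_fit(tb, binning, "osc_phase")$amplitude
}

#' Normalized tACS effect
#'
#' `(entamp_tacs - baseline_amp) / baseline_amp`; a value above 1 means the
#' tACS-phase entrainment amplitude is at least twice the baseline amplitude
#' of rhythmic fluctuation at that frequency (the responder criterion).
#'
#' @param entamp_tacs Entrainment amplitude to tACS phase.
#' @param baseline_amp Baseline amplitude from [baseline_amplitude()] (> 0).
#' @param floor Baselines below this value are flagged unstable (the ratio
#'   explodes as the baseline approaches 0); default `1e-3`.
#' @return Numeric value with attribute `unstable` when the baseline is
#'   below `floor`.
#' @export
normalized_effect <- function(entamp_tacs, baseline_amp, floor = 1e-3) {
  if (any(baseline_amp <= 0)) stop("normalized_effect: baseline must be > 0")
  out <- (entamp_tacs - baseline_amp) / baseline_amp
  if (any(baseline_amp < floor)) {
    attr(out, "unstable") <- baseline_amp < floor
    warning("normalized_effect: baseline below ", floor,
            "; normalization unstable")
  }
  out
}

#' Per-frequency tACS entrainment summary (noise stimuli)
#'
#' For every participant: fits the tACS-phase cosine per stimulation
#' frequency (entAmp-tACS, prefPhase-tACS), z-scores the amplitude against
#' accuracy-shuffle surrogates, computes the imaginary-oscillator baseline
#' at the same frequency from that participant's sham trials, the
#' normalized effect and the responder flag (normalized effect > 1 at a
#' frequency). A group-level Rayleigh test of the preferred phases is run
#' per frequency.
#'
#' @param table Full trial table (all participants) with sham and active
#'   conditions, as produced by the exp2 generator.
#' @param n_perm Accuracy-shuffle surrogates per fit (default 1000).
#' @param seed Integer seed.
#' @param binning tACS-phase binning (default 6 bins).
#' @return A `freq_effect_table`: data frame with one row per participant x
#'   frequency (`entamp_tacs`, `pref_phase_tacs`, `z`, `baseline_amp`,
#'   `normalized_effect`, `responder`), plus attributes `rayleigh` (list per
#'   frequency) and `responder_fraction` (participants with a normalized
#'   effect > 1 at one or more frequencies).
#' @export
exp2_summary <- function(table, n_perm = 1000, seed = 1,
                         binning = phase_binning(6)) {
  stopifnot(is.data.frame(table))
  freqs <- sort(unique(as.numeric(
    as.character(table$condition[table$condition != "sham"]))))
  if (length(freqs) == 0) stop("exp2_summary: no active tACS conditions")
  if (!any(table$condition == "sham")) stop("exp2_summary: no sham condition")
  pids <- sort(unique(table$participant))
  rows <- list()
  for (p in pids) {
    sham <- table[table$participant == p & table$condition == "sham", ]
    for (f in freqs) {
      sub <- table[table$participant == p &
                     table$condition == as.character(f), ]
      if (nrow(sub) == 0)
        stop("exp2_summary: participant ", p, " lacks condition ", f)
      br <- binned_hit_rates(sub, binning, "tacs_phase")
      fit <- fit_cosine(br$center, br$rate)
      null <- surrogate_null(sub, binning, "tacs_phase",
                             n_perm = n_perm,
                             seed = seed + 1000L * p + round(10 * f))
      base <- baseline_amplitude(sham, f, binning)
      ne <- suppressWarnings(normalized_effect(fit$amplitude, base))
      rows[[length(rows) + 1L]] <- data.frame(
        participant = p, freq = f,
        entamp_tacs = fit$amplitude, pref_phase_tacs = fit$phase,
        z = zscore_vs_null(fit$amplitude, null),
        baseline_amp = base, normalized_effect = as.numeric(ne),
        responder = as.numeric(ne) > 1)
    }
  }
  out <- do.call(rbind, rows)
  rayleigh <- lapply(stats::setNames(freqs, freqs), function(f)
    rayleigh_test(out$pref_phase_tacs[out$freq == f]))
  attr(out, "rayleigh") <- rayleigh
  attr(out, "responder_fraction") <-
    mean(vapply(pids, function(p) any(out$responder[out$participant == p]),
                logical(1)))
  class(out) <- c("freq_effect_table", "data.frame")
  out
}
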