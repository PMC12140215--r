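#' Design configuration for a simulated gap-detection experiment
#'
#' Encodes the session structure of the three experimental designs the
#' package targets:
#' \describe{
#'   \item{exp1}{FM-modulated tones plus 2-Hz tACS. Two modulation-depth
#'     conditions (one session each), 5 blocks x 32 stimuli x 3-5 gaps
#'     (about 136 gaps per block), gaps at the centers of 9 FM-phase bins,
#'     6 tACS lag bins, a sham stimulation condition interleaved at the
#'     stimulus level.}
#'   \item{exp2}{Unmodulated noise plus tACS at one of 0.8/2/3.2/4.4 Hz or
#'     sham, one block per condition.}
#'   \item{exp3}{FM tones at 4 rates, no tACS, gaps at the centers of 15
#'     FM-phase bins, 2 blocks x 28 stimuli per rate (56 stimuli/rate).}
#' }
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param n_participants Number of participants.
#' @param conditions Condition labels: modulation depth (%) for exp1, tACS
#'   frequency in Hz (or `"sham"`) for exp2, FM rate in Hz for exp3.
#' @param n_blocks Blocks per condition.
#' @param stimuli_per_block Stimuli (20-s sounds) per block.
#' @param stimulus_duration Stimulus length in seconds.
#' @param gap_range Integer range of gaps per stimulus, default 3-5.
#' @param n_fm_phase_bins FM-phase bins gaps are centered on.
#' @param n_tacs_lag_bins tACS lag bins (exp1).
#' @param fm_rate FM rate in Hz (exp1; exp3 rates come from `conditions`).
#' @param tacs_rate tACS frequency in Hz (exp1; exp2 frequencies come from
#'   `conditions`).
#' @param sham_prob Probability that a stimulus is a sham-stimulation
#'   stimulus (exp1: one of 7 interleaved stimulation conditions).
#' @param seed Integer seed; fully determines [gen_design()] output.
#' @return A `design_config` list.
#' @export
design_config <- function(experiment = c("exp1", "exp2", "exp3"),
                          n_participants = NULL, conditions = NULL,
                          n_blocks = NULL, stimuli_per_block = NULL,
                          stimulus_duration = 20, gap_range = c(3L, 5L),
                          n_fm_phase_bins = NULL, n_tacs_lag_bins = 6L,
                          fm_rate = 2, tacs_rate = 2, sham_prob = 1 / 7,
                          seed = 1L) {
  experiment <- match.arg(experiment)
  def <- switch(experiment,
    exp1 = list(n_participants = 27L, conditions = c("11", "39"),
                n_blocks = 5L, stimuli_per_block = 32L, n_fm_phase_bins = 9L),
    exp2 = list(n_participants = 24L,
                conditions = c("sham", "0.8", "2", "3.2", "4.4"),
                n_blocks = 1L, stimuli_per_block = 32L, n_fm_phase_bins = 9L),
    exp3 = list(n_participants = 12L, conditions = c("0.8", "2", "3.2", "4.4"),
                n_blocks = 2L, stimuli_per_block = 28L, n_fm_phase_bins = 15L))
  cfg <- list(
    experiment = experiment,
    n_participants = as.integer(n_participants %||% def$n_participants),
    conditions = as.character(conditions %||% def$conditions),
    n_blocks = as.integer(n_blocks %||% def$n_blocks),
    stimuli_per_block = as.integer(stimuli_per_block %||% def$stimuli_per_block),
    stimulus_duration = stimulus_duration,
    gap_range = as.integer(gap_range),
    n_fm_phase_bins = as.integer(n_fm_phase_bins %||% def$n_fm_phase_bins),
    n_tacs_lag_bins = as.integer(n_tacs_lag_bins),
    fm_rate = fm_rate, tacs_rate = tacs_rate, sham_prob = sham_prob,
    seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_participants >= 1, n_blocks >= 1, stimuli_per_block >= 1,
              stimulus_duration > 0, length(gap_range) == 2,
              gap_range[1] >= 1, gap_range[2] >= gap_range[1],
              n_fm_phase_bins >= 2, n_tacs_lag_bins >= 2)
  })
  # feasibility of gap packing: gaps live in (1, dur-1), >= 1.5 s apart
  if ((cfg$gap_range[2] - 1) * 1.5 >= cfg$stimulus_duration - 2)
    stop("design_config: cannot place ", cfg$gap_range[2],
         " gaps >= 1.5 s apart within (1, ", cfg$stimulus_duration - 1, ") s")
  structure(cfg, class = "design_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gap onset times for one stimulus: n gaps in (1, dur-1), >= min_sep apart
.pack_gaps <- function(n, dur, min_sep = 1.5) {
  lo <- 1; hi <- dur - 1
  slack <- (hi - lo) - (n - 1) * min_sep
  if (slack <= 0) stop("gap packing infeasible")
  sort(stats::runif(n, 0, slack)) + lo + min_sep * (seq_len(n) - 1)
}

#' Generate the trial skeleton of an experiment (no outcomes)
#'
#' Produces one row per gap with participant, session, condition, block,
#' gap onset time, and the phase columns the experiment defines. Outcome
#' columns (`accuracy`, `response_time`) are NA until filled by
#' [simulate_outcomes()]. Per participant and condition, FM-phase bins are
#' occupied near-uniformly (counts differ by at most 1); tACS lags (exp1)
#' are drawn uniformly on the circle per trial.
#'
#' @param config A [design_config()].
#' @return A `trial_table` data frame with attribute `config`. Columns:
#'   `participant`, `session`, `condition`, `block`, `stimulus`, `stim`
#'   (`"tacs"`/`"sham"`), `gap_time`, `fm_phase`, `tacs_phase`, `tacs_lag`,
#'   `response_time`, `accuracy`.
#' @export
gen_design <- function(config) {
  stopifnot(inherits(config, "design_config"))
  set.seed(config$seed)
  fmb <- phase_binning(config$n_fm_phase_bins)
  rows <- list()
  for (p in seq_len(config$n_participants)) {
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      n_stim <- config$n_blocks * config$stimuli_per_block
      n_gap_stim <- sample(seq(config$gap_range[1], config$gap_range[2]),
                           n_stim, replace = TRUE)
      n_gaps <- sum(n_gap_stim)
      block <- rep(rep(seq_len(config$n_blocks),
                       each = config$stimuli_per_block), times = 1)
      block <- rep(block, n_gap_stim)
      stim_id <- rep(seq_len(n_stim), n_gap_stim)
      gap_time <- unlist(lapply(n_gap_stim, .pack_gaps,
                                dur = config$stimulus_duration))
      # balanced FM-bin assignment within participant x condition
      fm_bin <- sample(rep(seq_len(fmb$n_bins), length.out = n_gaps))
      fm_phase <- fmb$centers[fm_bin]
      d <- data.frame(
        participant = p,
        session = if (config$experiment == "exp1") ci else 1L,
        condition = cond, block = block, stimulus = stim_id,
        stim = "tacs", gap_time = gap_time, fm_phase = fm_phase,
        tacs_phase = NA_real_, tacs_lag = NA_real_,
        response_time = NA_real_, accuracy = NA_real_)
      if (config$experiment == "exp1") {
        sham_stim <- stats::runif(n_stim) < config$sham_prob
        d$stim <- ifelse(sham_stim[stim_id], "sham", "tacs")
        lag <- wrap_phase(stats::runif(n_gaps, -pi, pi))
        act <- d$stim == "tacs"
        d$tacs_lag[act] <- lag[act]
        d$tacs_phase[act] <- wrap_phase(d$fm_phase[act] - lag[act])
      } else if (config$experiment == "exp2") {
        d$fm_phase <- NA_real_  # no FM rhythm in the noise stimuli
        d$stim <- if (cond == "sham") "sham" else "tacs"
        if (cond != "sham") {
          f <- as.numeric(cond)
          start_phase <- stats::runif(n_stim, -pi, pi)
          d$tacs_phase <- wrap_phase(2 * pi * f * d$gap_time +
                                       start_phase[stim_id])
        }
      }
      rows[[length(rows) + 1L]] <- d
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, config = config, class = c("trial_table", "data.frame"))
}

#' Behavioral generating model parameters
#'
#' Latent effect structure used by [simulate_outcomes()]: the hit
#' probability of each gap is an additive cosine of the relevant phase,
#' `p = clip(base_rate + A * cos(phase - pref), clip_eps, 1 - clip_eps)`,
#' where the amplitude `A` depends on the experiment:
#' \describe{
#'   \item{exp1}{`A = fm_amp[depth] * (1 + tacs_modulation * cos(tacs_lag -
#'     lag_opt))` on FM phase; the lag-dependent gain is absent for sham
#'     trials. `lag_opt` is a per-participant latent optimal lag.}
#'   \item{exp2}{`A = tacs_peak_amp * exp(-(log2 f - log2 f_res)^2 /
#'     (2 * tuning_width^2))` on tACS phase (Gaussian tuning in
#'     log-frequency around the participant's latent resonance frequency
#'     `f_res`); sham trials carry an intrinsic behavioral oscillation of
#'     amplitude `intrinsic_amp` at `f_res`, phase-locked to stimulus onset.}
#'   \item{exp3}{`A = fm_amp + amp_slope_per_hz * rate` on FM phase.}
#' }
#'
#' @param base_rate Baseline hit probability (threshold-tracked task; 0.5).
#' @param fm_amp Cosine amplitude in probability units. For exp1, a named
#'   vector by modulation-depth condition.
#' @param fm_pref_phase Preferred FM phase (radians); `NA` draws one latent
#'   preferred phase per participant.
#' @param tacs_modulation Gain of the tACS-lag modulation of `fm_amp` (exp1).
#' @param lag_opt Optimal tACS lag (radians); `NA` draws per participant.
#' @param tacs_peak_amp Peak tACS-phase amplitude at resonance (exp2).
#' @param resonance_freq Latent resonance frequency in Hz; `NA` draws per
#'   participant log-uniformly on `resonance_range`.
#' @param resonance_range Range resonance frequencies are drawn from (Hz).
#' @param tuning_width Gaussian tuning width in octaves (exp2).
#' @param intrinsic_amp Sham-condition intrinsic rhythm amplitude (exp2).
#' @param amp_slope_per_hz Increase of FM entrainment amplitude per Hz of FM
#'   rate (exp3).
#' @param clip_eps Probability floor/ceiling margin.
#' @return A `behavioral_params` list.
#' @export
behavioral_params <- function(base_rate = 0.5,
                              fm_amp = c("11" = 0.04, "39" = 0.08),
                              fm_pref_phase = NA, tacs_modulation = 0.5,
                              lag_opt = NA, tacs_peak_amp = 0.08,
                              resonance_freq = NA,
                              resonance_range = c(0.8, 4.4),
                              tuning_width = 0.6, intrinsic_amp = 0.03,
                              amp_slope_per_hz = 0.015, clip_eps = 0.02) {
  stopifnot(base_rate > 0, base_rate < 1, all(fm_amp >= 0),
            tacs_peak_amp >= 0, tuning_width > 0, clip_eps >= 0,
            clip_eps < 0.5)
  structure(as.list(environment()), class = "behavioral_params")
}

.gauss_tuning <- function(f, f_res, width) {
  exp(-(log2(f) - log2(f_res))^2 / (2 * width^2))
}

#' Simulate gap-detection outcomes on a trial skeleton
#'
#' Fills `accuracy` by Bernoulli draws from the additive-cosine hit model of
#' [behavioral_params()] and `response_time` for hits (uniform 0.2-1.0 s).
#' Per-participant latents (preferred phases, optimal lag, resonance
#' frequency) are drawn from `seed` and stored in `attr(, "latents")`;
#' `attr(, "n_clipped")` counts probabilities that hit the clip bounds.
#'
#' @param table A `trial_table` from [gen_design()].
#' @param params A [behavioral_params()].
#' @param seed Integer seed for latents and Bernoulli draws.
#' @return The table with outcomes filled.
#' @export
simulate_outcomes <- function(table, params = behavioral_params(), seed = 1) {
  stopifnot(inherits(table, "trial_table"), inherits(params, "behavioral_params"))
  cfg <- attr(table, "config")
  set.seed(as.integer(seed))
  np <- max(table$participant)
  lat <- list(
    fm_pref = if (is.na(params$fm_pref_phase))
      wrap_phase(stats::runif(np, -pi, pi)) else rep(params$fm_pref_phase, np),
    lag_opt = if (is.na(params$lag_opt))
      wrap_phase(stats::runif(np, -pi, pi)) else rep(params$lag_opt, np),
    resonance = if (is.na(params$resonance_freq))
      2^stats::runif(np, log2(params$resonance_range[1]),
                     log2(params$resonance_range[2]))
      else rep(params$resonance_freq, np))
  pid <- table$participant
  p <- switch(cfg$experiment,
    exp1 = {
      amp <- params$fm_amp[as.character(table$condition)]
      gain <- ifelse(table$stim == "sham", 1,
                     1 + params$tacs_modulation *
                       cos(table$tacs_lag - lat$lag_opt[pid]))
      params$base_rate + amp * gain * cos(table$fm_phase - lat$fm_pref[pid])
    },
    exp2 = {
      f_res <- lat$resonance[pid]
      act <- table$stim == "tacs"
      pr <- rep(params$base_rate, nrow(table))
      f <- suppressWarnings(as.numeric(as.character(table$condition)))
      pr[act] <- params$base_rate +
        params$tacs_peak_amp * .gauss_tuning(f[act], f_res[act],
                                             params$tuning_width) *
        cos(table$tacs_phase[act] - lat$fm_pref[pid[act]])
      sham <- !act
      pr[sham] <- params$base_rate + params$intrinsic_amp *
        cos(2 * pi * f_res[sham] * table$gap_time[sham] -
              lat$fm_pref[pid[sham]])
      pr
    },
    exp3 = {
      rate <- as.numeric(as.character(table$condition))
      amp <- params$fm_amp[[1]] + params$amp_slope_per_hz * rate
      params$base_rate + amp * cos(table$fm_phase - lat$fm_pref[pid])
    })
  n_clipped <- sum(p < params$clip_eps | p > 1 - params$clip_eps)
  if (n_clipped > 0 && params$clip_eps == 0)
    stop("simulate_outcomes: probabilities saturate with clip_eps = 0")
  p <- pmin(pmax(p, params$clip_eps), 1 - params$clip_eps)
  table$accuracy <- stats::rbinom(nrow(table), 1, p)
  table$response_time <- ifelse(table$accuracy == 1,
                                stats::runif(nrow(table), 0.2, 1.0), NA_real_)
  attr(table, "latents") <- lat
  attr(table, "hit_prob") <- p
  attr(table, "n_clipped") <- n_clipped
  table
}

#' Score button presses against gap onsets
#'
#' A gap counts as a hit when a press falls later than 100 ms and no later
#' than 1,500 ms after its onset; each press is credited to at most one gap
#' (earliest gap first, first unused press in the window wins). Presses that
#' do not fall inside any gap's response window are false alarms.
#'
#' @param gap_times Sorted gap onset times (s) within one stimulus.
#' @param press_times Sorted button-press times (s).
#' @param window Response window (s after gap onset), default `c(0.1, 1.5)`
#'   (open at the left edge, closed at the right).
#' @return List with `accuracy` (0/1 per gap), `response_time` (press minus
#'   gap onset, NA for misses), `false_alarms` (count), `fa_times`.
#' @export
classify_responses <- function(gap_times, press_times,
                               window = c(0.1, 1.5)) {
  if (any(gap_times < 0) || any(press_times < 0))
    stop("classify_responses: negative times")
  if (is.unsorted(gap_times) || is.unsorted(press_times))
    stop("classify_responses: times must be sorted")
  used <- rep(FALSE, length(press_times))
  acc <- integer(length(gap_times))
  rt <- rep(NA_real_, length(gap_times))
  for (i in seq_along(gap_times)) {
    ok <- !used & press_times > gap_times[i] + window[1] &
      press_times <= gap_times[i] + window[2]
    j <- which(ok)[1]
    if (!is.na(j)) {
      used[j] <- TRUE
      acc[i] <- 1L
      rt[i] <- press_times[j] - gap_times[i]
    }
  }
  in_any_window <- vapply(press_times, function(tp)
    any(tp > gap_times + window[1] & tp <= gap_times + window[2]),
    logical(1))
  fa <- press_times[!in_any_window]
  list(accuracy = acc, response_time = rt,
       false_alarms = length(fa), fa_times = fa)
}

#' Simulate a raw button-press stream for one stimulus
#'
#' Hits produce a press 0.2-1.0 s after the gap; false alarms arrive as a
#' homogeneous Poisson process over the stimulus.
#'
#' @param gap_times Gap onsets (s).
#' @param p_hit Hit probability per gap.
#' @param duration Stimulus duration (s).
#' @param fa_rate False alarms per second.
#' @param seed Integer seed.
#' @return Sorted press times (s).
#' @export
simulate_press_stream <- function(gap_times, p_hit = 0.7, duration = 20,
                                  fa_rate = 0.01, seed = 1) {
  set.seed(as.integer(seed))
  hits <- stats::runif(length(gap_times)) < p_hit
  presses <- gap_times[hits] + stats::runif(sum(hits), 0.2, 1.0)
  n_fa <- stats::rpois(1, fa_rate * duration)
  sort(c(presses, stats::runif(n_fa, 0, duration)))
}

#' Simulate phase-locked EEG-like epochs
#'
#' Each epoch is `locked_amp * cos(2*pi*freq*t + phi)` plus 1/f^alpha noise,
#' where `phi` is a per-trial phase: the common onset phase plus wrapped
#' Gaussian jitter of SD `phase_jitter_sd` (0 = perfectly phase-locked).
#' All channels share the locked component; noise is independent per trial
#' and channel and scaled to RMS `noise_amp`.
#'
#' @param n_trials Number of epochs.
#' @param freq Locked-component frequency (Hz); must be below `fs / 2`.
#' @param fs Sampling rate (Hz), default 500.
#' @param duration Epoch length (s), default 10 (so that 0.8/2/3.2/4.4 Hz
#'   all fall exactly on 0.1-Hz Fourier bins).
#' @param locked_amp Amplitude of the phase-locked sinusoid.
#' @param noise_amp RMS of the additive noise.
#' @param noise_exponent Spectral exponent alpha of the 1/f^alpha noise.
#' @param phase_jitter_sd Per-trial phase jitter SD in radians.
#' @param onset_phase Phase of the locked component at sample 0.
#' @param channel_labels Channel names; defaults to the 9-channel
#'   fronto-central cluster.
#' @param seed Integer seed.
#' @return An `epoch_set`: list with `data` (trials x channels x samples
#'   array), `fs`, `condition` (= `freq`), `channel_labels`, `onset_phase`.
#' @export
simulate_eeg_epochs <- function(n_trials, freq, fs = 500, duration = 10,
                                locked_amp = 1, noise_amp = 1,
                                noise_exponent = 1, phase_jitter_sd = 0,
                                onset_phase = 0,
                                channel_labels = fronto_central_cluster(),
                                seed = 1) {
  if (freq >= fs / 2) stop("simulate_eeg_epochs: freq must be < fs/2")
  stopifnot(n_trials >= 1, duration > 0)
  set.seed(as.integer(seed))
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  nc <- length(channel_labels)
  dat <- array(0, dim = c(n_trials, nc, n))
  phi <- onset_phase + if (phase_jitter_sd > 0)
    stats::rnorm(n_trials, 0, phase_jitter_sd) else numeric(n_trials)
  for (tr in seq_len(n_trials)) {
    locked <- locked_amp * cos(2 * pi * freq * t + phi[tr])
    for (ch in seq_len(nc)) {
      noise <- if (noise_amp > 0)
        noise_amp * .pink_noise(n, fs, noise_exponent) else numeric(n)
      dat[tr, ch, ] <- locked + noise
    }
  }
  structure(list(data = dat, fs = fs, condition = freq,
                 channel_labels = channel_labels,
                 onset_phase = onset_phase),
            class = "epoch_set")
}

# unit-RMS 1/f^alpha noise via spectral shaping of white noise
.pink_noise <- function(n, fs, alpha) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1)) * fs / n  # avoid DC blow-up
  f <- pmin(f, fs - f)                # two-sided spectrum symmetry
  X <- X / f^(alpha / 2)
  X[1] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Standard fronto-central electrode cluster
#'
#' The 9-channel set over which evoked amplitude and intertrial coherence
#' are averaged (typical auditory topography).
#' @return Character vector of channel labels.
#' @export
fronto_central_cluster <- function() {
  c("F3", "Fz", "F4", "FC1", "FCz", "FC2", "C3", "Cz", "C4")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch set: %d trials x %d channels x %d samples @ %g Hz, condition %g Hz\n",
              d[1], d[2], d[3], x$fs, x$condition))
  invisible(x)
}
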