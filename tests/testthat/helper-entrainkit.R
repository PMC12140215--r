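# Lightweight trial-table construction for estimator tests: rows drawn at
# phase-bin centers with Bernoulli outcomes from an additive-cosine model.
make_phase_table <- function(n, n_bins = 9, base = 0.5, amp = 0.2,
                             pref = pi / 2, phase_col = "fm_phase",
                             seed = 1) {
  set.seed(seed)
  b <- phase_binning(n_bins)
  ph <- sample(b$centers, n, replace = TRUE)
  p <- base + amp * cos(ph - pref)
  d <- data.frame(participant = 1L, session = 1L, condition = "x",
                  block = 1L, stimulus = 1L, stim = "tacs",
                  gap_time = runif(n, 1, 19), fm_phase = NA_real_,
                  tacs_phase = NA_real_, tacs_lag = NA_real_,
                  response_time = NA_real_,
                  accuracy = rbinom(n, 1, p))
  d[[phase_col]] <- ph
  structure(d, class = c("trial_table", "data.frame"))
}

# One participant's Experiment-1-scale active+sham table without the
# stimulus-packing machinery: balanced FM bins, uniform tACS lags.
exp1_participant_table <- function(n_gaps = 680, n_fm = 9, base = 0.5,
                                   fm_amp = 0.06, tacs_mod = 0,
                                   lag_opt = 0, pref = 0, sham_frac = 1 / 7,
                                   seed = 1) {
  set.seed(seed)
  b <- phase_binning(n_fm)
  fm <- b$centers[sample(rep(seq_len(n_fm), length.out = n_gaps))]
  lag <- wrap_phase(runif(n_gaps, -pi, pi))
  sham <- runif(n_gaps) < sham_frac
  amp <- fm_amp * ifelse(sham, 1, 1 + tacs_mod * cos(lag - lag_opt))
  p <- pmin(pmax(base + amp * cos(fm - pref), 0.02), 0.98)
  d <- data.frame(participant = 1L, session = 1L, condition = "11",
                  block = 1L, stimulus = 1L,
                  stim = ifelse(sham, "sham", "tacs"),
                  gap_time = runif(n_gaps, 1, 19), fm_phase = fm,
                  tacs_phase = wrap_phase(fm - lag), tacs_lag = lag,
                  response_time = NA_real_,
                  accuracy = rbinom(n_gaps, 1, p))
  d$tacs_phase[sham] <- NA_real_
  d$tacs_lag[sham] <- NA_real_
  structure(d, class = c("trial_table", "data.frame"))
}

# Brute-force oracle for the cosine fit: dense 2-D grid search over
# (amplitude, phase) with the offset profiled out analytically.
grid_search_cosine <- function(centers, rates, amp_max = 1,
                               n_amp = 400, n_phase = 720) {
  best <- NULL
  best_ss <- Inf
  for (a in seq(0, amp_max, length.out = n_amp)) {
    for (ph in seq(-pi, pi, length.out = n_phase + 1)[-(n_phase + 1)]) {
      mu <- a * cos(centers - ph)
      off <- mean(rates - mu)
      ss <- sum((rates - off - mu)^2)
      if (ss < best_ss) {
        best_ss <- ss
        best <- c(offset = off, amplitude = a, phase = ph)
      }
    }
  }
  best
}
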