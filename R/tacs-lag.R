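#' Instantaneous tACS phase from a recorded stimulation channel
#'
#' Zero-phase band-pass (4th-order Butterworth, forward-backward) between
#' `band[1]` and `band[2]` Hz, followed by the analytic signal; the phase is
#' the angle of the analytic signal, so a pure cosine has phase 0 at its
#' peaks and the unwrapped phase advances at the oscillation frequency.
#'
#' @param x Sampled voltage trace.
#' @param fs Sampling rate in Hz (> 20).
#' @param band Pass band in Hz, default `c(1, 10)`.
#' @return Phase series in radians, wrapped to `[-pi, pi)`.
#' @export
extract_tacs_phase <- function(x, fs, band = c(1, 10)) {
  if (fs <= 20) stop("extract_tacs_phase: fs must exceed 20 Hz")
  if (length(x) < 2 * fs) stop("extract_tacs_phase: need >= 2 s of signal")
  if (stats::sd(x) == 0) stop("extract_tacs_phase: constant signal, phase undefined")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  wrap_phase(Arg(.analytic_signal(xf)))
}

# analytic signal via one-sided spectrum doubling
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' FM-tACS phase lag and lag bin
#'
#' The lag is the angular separation `wrap(fm_phase - tacs_phase)`; it is
#' attributed to one of `n_bins` equally spaced circular bins.
#'
#' @param fm_phase,tacs_phase Wrapped phases in radians.
#' @param n_bins Number of lag bins (default 6).
#' @return Data frame with `lag` (radians) and `lag_bin` (1-based index).
#' @export
lag_binning <- function(fm_phase, tacs_phase, n_bins = 6) {
  lag <- wrap_phase(fm_phase - tacs_phase)
  data.frame(lag = lag, lag_bin = bin_phase(lag, phase_binning(n_bins)))
}

# 3 x n pseudo-inverse of the [1, cos, sin] basis at fixed centers
.cos_basis <- function(centers) {
  X <- cbind(1, cos(centers), sin(centers))
  solve(crossprod(X), t(X))
}

# fast closed-form cosine fit given the precomputed pseudo-inverse
.cos_fit_fast <- function(P, vals) {
  b <- P %*% vals
  list(offset = b[1], amplitude = sqrt(b[2]^2 + b[3]^2),
       phase = if (b[2] == 0 && b[3] == 0) 0 else atan2(b[3], b[2]))
}

# entrainment amplitude per lag bin from integer-coded bins (fast kernel).
# Observed data require every FM x lag cell non-empty (participants failing
# this are excluded); surrogate lag shuffles can empty a cell by chance, in
# which case allow_empty = TRUE fits that lag bin on its available FM bins.
.lag_profile_amps <- function(fm_idx, lag_idx, acc, n_fm, n_lag, P_fm,
                              centers_fm = NULL, allow_empty = FALSE) {
  amps <- numeric(n_lag)
  cell <- (lag_idx - 1L) * n_fm + fm_idx
  n <- tabulate(cell, nbins = n_fm * n_lag)
  hits <- numeric(n_fm * n_lag)
  pos <- which(n > 0L)
  hits[pos] <- rowsum(acc, cell, reorder = TRUE)
  if (any(n == 0L) && !allow_empty) {
    bad <- which(n == 0L)[1]
    stop(sprintf("empty cell: FM bin %d x lag bin %d",
                 (bad - 1L) %% n_fm + 1L, (bad - 1L) %/% n_fm + 1L))
  }
  for (l in seq_len(n_lag)) {
    ix <- ((l - 1L) * n_fm + 1L):(l * n_fm)
    nl <- n[ix]
    if (all(nl > 0L)) {
      b <- P_fm[2:3, , drop = FALSE] %*% (hits[ix] / nl)
      amps[l] <- sqrt(sum(b^2))
    } else {
      keep <- nl > 0L
      if (sum(keep) < 3L)
        stop("lag bin ", l, ": fewer than 3 occupied FM bins")
      X <- cbind(1, cos(centers_fm[keep]), sin(centers_fm[keep]))
      b <- qr.coef(qr(X), hits[ix][keep] / nl[keep])
      amps[l] <- sqrt(b[2]^2 + b[3]^2)
    }
  }
  amps
}

#' FM-entrainment amplitude profile over tACS lag bins
#'
#' Bins each gap by FM phase (9 bins) and FM-tACS lag (6 bins), computes hit
#' rates in every FM-by-lag cell, and fits a first-level cosine over FM
#' phase within each lag bin. The fitted amplitudes form the entrainment
#' profile over tACS lag. Every cell must contain at least one gap,
#' mirroring the exclusion of participants with empty cells.
#'
#' @param table Trial table for one participant/condition with populated
#'   `fm_phase`, `tacs_lag` and `accuracy` (active-stimulation rows only).
#' @param n_fm_bins FM-phase bins (default 9).
#' @param n_lag_bins tACS lag bins (default 6).
#' @return A `lag_profile`: `lag_centers`, `entamp` (one amplitude per lag
#'   bin), `fits` (per-lag `cosine_fit`s), and bin metadata.
#' @export
profile_entrainment_by_lag <- function(table, n_fm_bins = 9, n_lag_bins = 6) {
  stopifnot(is.data.frame(table))
  if (any(is.na(table$tacs_lag)))
    stop("profile_entrainment_by_lag: NA tACS lag (sham rows present?)")
  fmb <- phase_binning(n_fm_bins)
  lgb <- phase_binning(n_lag_bins)
  fm_idx <- bin_phase(table$fm_phase, fmb)
  lag_idx <- bin_phase(table$tacs_lag, lgb)
  fits <- vector("list", n_lag_bins)
  entamp <- numeric(n_lag_bins)
  for (l in seq_len(n_lag_bins)) {
    sub <- table[lag_idx == l, , drop = FALSE]
    br <- tryCatch(binned_hit_rates(sub, fmb, "fm_phase"),
                   error = function(e)
                     stop(sprintf("empty cell in lag bin %d: %s", l,
                                  conditionMessage(e)), call. = FALSE))
    fits[[l]] <- fit_cosine(br$center, br$rate)
    entamp[l] <- fits[[l]]$amplitude
  }
  structure(list(lag_centers = lgb$centers, entamp = entamp, fits = fits,
                 n_fm_bins = n_fm_bins, n_lag_bins = n_lag_bins),
            class = "lag_profile")
}

#' Second-level cosine fit: the optimal tACS lag
#'
#' Fits a cosine to the FM-entrainment amplitudes as a function of tACS lag;
#' the fitted phase is the lag at which the predicted FM-entrainment
#' amplitude is highest (the individually optimal tACS lag).
#'
#' @param profile A `lag_profile`.
#' @return A `cosine_fit` whose `phase` is the optimal lag; `degenerate` is
#'   TRUE for a flat profile.
#' @export
second_level_fit <- function(profile) {
  stopifnot(inherits(profile, "lag_profile"))
  fit_cosine(profile$lag_centers, profile$entamp)
}

#' Realign a lag profile to its optimal lag
#'
#' The bin whose center is closest to the optimal lag (ties broken toward
#' the lower bin index) is relabeled as zero lag, and the remaining bins are
#' rotated around the circle. To avoid selection bias, the realigned zero
#' bin and its opposite (pi) are excluded from further analysis.
#'
#' @param profile A `lag_profile`.
#' @param optimal_lag Optimal lag in radians (from [second_level_fit()]).
#' @return List with `centers` (realigned bin centers, starting at 0),
#'   `values` (entrainment amplitudes in realigned order), `excluded`
#'   (logical mask: zero bin and its opposite), `shift` (bins rotated).
#' @export
realign_profile <- function(profile, optimal_lag) {
  stopifnot(inherits(profile, "lag_profile"))
  n <- profile$n_lag_bins
  d <- abs(wrap_phase(optimal_lag - profile$lag_centers))
  k <- which.min(d)  # ties: lowest index
  ord <- ((k - 1L + seq_len(n) - 1L) %% n) + 1L
  centers <- phase_binning(n)$centers  # 0, 2pi/n, ... wrapped
  excluded <- abs(centers) < 1e-9 | abs(abs(centers) - pi) < 1e-9
  list(centers = centers, values = profile$entamp[ord],
       excluded = excluded, shift = k - 1L)
}

#' tACS half-cycle summaries of a realigned profile
#'
#' Averages the two retained bins adjacent to the realigned zero lag
#' (the optimal half-cycle, tACS(+)) and the two adjacent to its opposite
#' (tACS(-)).
#'
#' @param realigned Output of [realign_profile()].
#' @return List with `tacs_plus` and `tacs_minus`.
#' @export
half_cycle_summary <- function(realigned) {
  centers <- realigned$centers
  if (length(centers) %% 2 != 0)
    stop("half_cycle_summary: need an even number of lag bins")
  keep <- !realigned$excluded
  adj0 <- keep & abs(abs(wrap_phase(centers)) - 2 * pi / length(centers)) < 1e-9
  adjpi <- keep & !adj0
  if (sum(adj0) != 2 || sum(adjpi) != 2)
    stop("half_cycle_summary: expected 2 bins adjacent to 0 and 2 adjacent to pi")
  list(tacs_plus = mean(realigned$values[adj0]),
       tacs_minus = mean(realigned$values[adjpi]))
}

# full lag pipeline on integer-coded data; returns c(plus, minus)
.half_cycles_fast <- function(fm_idx, lag_idx, acc, n_fm, n_lag,
                              P_fm, P_lag, lag_centers, centers_fm = NULL,
                              allow_empty = FALSE) {
  amps <- .lag_profile_amps(fm_idx, lag_idx, acc, n_fm, n_lag, P_fm,
                            centers_fm, allow_empty)
  f2 <- .cos_fit_fast(P_lag, amps)
  d <- abs(wrap_phase(f2$phase - lag_centers))
  k <- which.min(d)
  ord <- ((k - 1L + seq_len(n_lag) - 1L) %% n_lag) + 1L
  vals <- amps[ord]
  # positions 2 and n adjoin realigned 0; positions around n/2+1 adjoin pi
  half <- n_lag %/% 2
  c(plus = mean(vals[c(2L, n_lag)]),
    minus = mean(vals[c(half, half + 2L)]))
}

#' Surrogate-normalized tACS effect for one participant and condition
#'
#' Runs the full Experiment-1 pipeline (FM-by-lag binning, first- and
#' second-level cosine fits, realignment with peak/trough exclusion,
#' half-cycle averaging) on the observed data, then on `n_perm` surrogate
#' datasets obtained by shuffling the tACS lag label across trials while
#' keeping everything else fixed. Observed data must fill all FM-by-lag
#' cells (participants with empty cells are excluded upstream); a surrogate
#' shuffle that happens to empty a cell fits that lag bin on its remaining
#' FM bins instead of aborting. The three contrasts tACS(+) - sham,
#' tACS(-) - sham and tACS(+) - tACS(-) are z-scored against their
#' surrogate distributions.
#'
#' @param table Trial table for one participant and condition containing
#'   both active (`stim == "tacs"`) and sham rows.
#' @param n_perm Number of lag-shuffle surrogates (default 1000).
#' @param seed Integer seed.
#' @param n_fm_bins,n_lag_bins Binning resolution (9 and 6).
#' @return A `tacs_effect` list: observed `tacs_plus`, `tacs_minus`,
#'   `sham_amp`, `optimal_lag`, the three `contrasts`, their `z` scores and
#'   the surrogate summary (`surrogate_mean`, `surrogate_sd`).
#' @export
tacs_effect_zscores <- function(table, n_perm = 1000, seed = 1,
                                n_fm_bins = 9, n_lag_bins = 6) {
  stopifnot(is.data.frame(table))
  act <- table[table$stim == "tacs", , drop = FALSE]
  sham <- table[table$stim == "sham", , drop = FALSE]
  if (nrow(sham) == 0) stop("tacs_effect_zscores: no sham trials")
  fmb <- phase_binning(n_fm_bins)
  lgb <- phase_binning(n_lag_bins)
  sham_amp <- entrainment_fit(sham, fmb, "fm_phase")$amplitude

  fm_idx <- bin_phase(act$fm_phase, fmb)
  lag_idx <- bin_phase(act$tacs_lag, lgb)
  acc <- act$accuracy
  P_fm <- .cos_basis(fmb$centers)
  P_lag <- .cos_basis(lgb$centers)

  obs <- .half_cycles_fast(fm_idx, lag_idx, acc, n_fm_bins, n_lag_bins,
                           P_fm, P_lag, lgb$centers)
  prof <- profile_entrainment_by_lag(act, n_fm_bins, n_lag_bins)
  opt <- second_level_fit(prof)$phase

  set.seed(as.integer(seed))
  sur <- matrix(NA_real_, n_perm, 2)
  for (i in seq_len(n_perm)) {
    sur[i, ] <- .half_cycles_fast(fm_idx, lag_idx[sample.int(length(lag_idx))],
                                  acc, n_fm_bins, n_lag_bins,
                                  P_fm, P_lag, lgb$centers,
                                  centers_fm = fmb$centers,
                                  allow_empty = TRUE)
  }
  obs_con <- c(plus_minus_sham = unname(obs["plus"] - sham_amp),
               minus_minus_sham = unname(obs["minus"] - sham_amp),
               plus_minus_minus = unname(obs["plus"] - obs["minus"]))
  sur_con <- cbind(plus_minus_sham = sur[, 1] - sham_amp,
                   minus_minus_sham = sur[, 2] - sham_amp,
                   plus_minus_minus = sur[, 1] - sur[, 2])
  mu <- colMeans(sur_con)
  sdv <- apply(sur_con, 2, stats::sd)
  if (any(!is.finite(sdv)) || any(sdv <= 0))
    stop("tacs_effect_zscores: degenerate surrogate distribution")
  structure(list(tacs_plus = unname(obs["plus"]),
                 tacs_minus = unname(obs["minus"]),
                 sham_amp = sham_amp, optimal_lag = opt,
                 contrasts = obs_con, z = (obs_con - mu) / sdv,
                 surrogate_mean = mu, surrogate_sd = sdv,
                 n_perm = n_perm),
            class = "tacs_effect")
}

#' @export
print.tacs_effect <- function(x, ...) {
  cat(sprintf(paste0("tACS effect: tACS(+) %.4f, tACS(-) %.4f, sham %.4f\n",
                     "  z: +vs sham %.2f, - vs sham %.2f, + vs - %.2f (%d surrogates)\n"),
              x$tacs_plus, x$tacs_minus, x$sham_amp,
              x$z[1], x$z[2], x$z[3], x$n_perm))
  invisible(x)
}
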