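#' Stuart-Landau oscillator parameters
#'
#' A canonical two-variable limit-cycle model of two coupled neural
#' populations:
#' \deqn{dx/dt = \lambda x - \omega y - \gamma(x^2+y^2)x + k s(t)}
#' \deqn{dy/dt = \lambda y + \omega x - \gamma(x^2+y^2)y}
#' with `s(t)` a zero-phase sine drive at `drive_freq` Hz switched on at
#' `drive_onset`. For `k = 0` the limit-cycle amplitude is
#' `sqrt(lambda/gamma)` (about 0.447 at the defaults). The drive strength
#' `k` is expressed as a fraction of that baseline amplitude; internally the
#' additive drive coefficient is `k * sqrt(lambda/gamma)`. `omega` is given
#' in Hz and converted to angular frequency internally.
#'
#' @param omega Intrinsic oscillator frequency in Hz.
#' @param k Drive strength as a fraction of the baseline amplitude (>= 0).
#' @param drive_freq Drive (tACS) frequency in Hz.
#' @param lambda Growth rate (default 0.2).
#' @param gamma Damping (default 1.0, > 0).
#' @param drive_onset Drive onset time in s (default 10).
#' @param x0,y0 Initial state (defaults 0, -1).
#' @return An `oscillator_params` list.
#' @export
oscillator_params <- function(omega, k = 0, drive_freq = 2, lambda = 0.2,
                              gamma = 1.0, drive_onset = 10,
                              x0 = 0, y0 = -1) {
  stopifnot(gamma > 0, k >= 0, omega > 0, drive_freq > 0, drive_onset >= 0)
  structure(list(omega = omega, k = k, drive_freq = drive_freq,
                 lambda = lambda, gamma = gamma, drive_onset = drive_onset,
                 x0 = x0, y0 = y0),
            class = "oscillator_params")
}

#' Integrate the driven Stuart-Landau oscillator
#'
#' Adaptive Runge-Kutta (Dormand-Prince 4/5) integration of the model via a
#' compiled right-hand side, relative tolerance `1e-6`.
#'
#' @param params An [oscillator_params()].
#' @param duration Total simulated time in s (> `drive_onset` when `k > 0`).
#' @param dt_out Output sampling step in s (default 0.01).
#' @param rtol,atol Integrator tolerances.
#' @return Data frame with `time`, `x`, `y`.
#' @export
integrate_oscillator <- function(params, duration = 30, dt_out = 0.01,
                                 rtol = 1e-6, atol = 1e-8) {
  stopifnot(inherits(params, "oscillator_params"))
  if (params$k > 0 && duration <= params$drive_onset)
    stop("integrate_oscillator: duration must exceed drive_onset")
  base_amp <- sqrt(abs(params$lambda) / params$gamma)
  parms <- c(params$lambda, 2 * pi * params$omega, params$gamma,
             params$k * base_amp, params$drive_freq, params$drive_onset)
  out <- deSolve::ode(y = c(params$x0, params$y0),
                      times = seq(0, duration, by = dt_out),
                      func = "sl_derivs", parms = parms,
                      dllname = "entrainkit", initfunc = "sl_init",
                      method = "ode45", rtol = rtol, atol = atol)
  if (any(!is.finite(out)))
    stop("integrate_oscillator: non-finite state (omega=", params$omega,
         ", k=", params$k, ", drive=", params$drive_freq, ")")
  data.frame(time = out[, 1], x = out[, 2], y = out[, 3])
}

#' Post-transient oscillation amplitude
#'
#' Mean envelope `sqrt(x^2 + y^2)` over a time window.
#'
#' @param traj Trajectory from [integrate_oscillator()].
#' @param from,to Window bounds in s.
#' @return Scalar amplitude.
#' @export
oscillation_amplitude <- function(traj, from, to = Inf) {
  w <- traj$time >= from & traj$time <= to
  if (!any(w)) stop("oscillation_amplitude: empty window")
  mean(sqrt(traj$x[w]^2 + traj$y[w]^2))
}

#' Entrainment change due to the drive
#'
#' Percent change of the oscillation amplitude (mean envelope
#' `sqrt(x^2+y^2)`) caused by the drive:
#' `(A_drive - A_base) / A_base * 100`, where both amplitudes are measured
#' over the same post-transient analysis window
#' (`drive_onset + transient` to `duration`), `A_drive` on the driven run
#' and `A_base` on a matched undriven (`k = 0`) run. Comparing matched runs
#' over the same window cancels the relaxation transient of the initial
#' condition, so the change is identically 0 for `k = 0`; a drive near the
#' intrinsic frequency grows the amplitude (Arnold-tongue resonance).
#'
#' @param params An [oscillator_params()].
#' @param duration Total simulated time (default 30 s, drive on at 10 s).
#' @param transient Seconds discarded after drive onset (default 5).
#' @param dt_out Output step (default 0.01 s).
#' @param baseline Optional precomputed baseline amplitude for this omega
#'   (used by [sweep_oscillator()] to avoid repeating undriven runs).
#' @return Percent change (scalar).
#' @export
entrainment_change <- function(params, duration = 30, transient = 5,
                               dt_out = 0.01, baseline = NULL) {
  stopifnot(inherits(params, "oscillator_params"))
  on <- params$drive_onset
  if (duration - on - transient < 2 / params$drive_freq)
    stop("entrainment_change: analysis window shorter than 2 drive cycles")
  from <- on + transient
  traj <- integrate_oscillator(params, duration, dt_out)
  a_drive <- oscillation_amplitude(traj, from, duration)
  if (is.null(baseline)) {
    p0 <- params
    p0$k <- 0
    baseline <- oscillation_amplitude(
      integrate_oscillator(p0, duration, dt_out), from, duration)
  }
  (a_drive - baseline) / baseline * 100
}

#' Entrainment-change sweep over the (omega, k) grid
#'
#' Integrates the model for every combination of intrinsic frequency,
#' relative drive strength and drive frequency and records the percent
#' entrainment change. Defaults follow the published grid: omega 0.1-8 Hz
#' in 0.1-Hz steps, k 0-100% in 10% steps, drives at 0.8/2/3.2/4.4 Hz
#' (3,520 cells). Deterministic; cache the result for reuse.
#'
#' @param omega_grid Intrinsic frequencies in Hz.
#' @param k_grid Drive strengths as fractions of the baseline amplitude.
#' @param drive_freqs Drive frequencies in Hz.
#' @param duration,transient,dt_out Passed to [entrainment_change()].
#' @return A `sweep_result`: `omega_grid`, `k_grid`, `drive_freqs`, and
#'   `change` (array omega x k x drive, percent).
#' @export
sweep_oscillator <- function(omega_grid = seq(0.1, 8, by = 0.1),
                             k_grid = seq(0, 1, by = 0.1),
                             drive_freqs = c(0.8, 2, 3.2, 4.4),
                             duration = 30, transient = 5, dt_out = 0.01) {
  stopifnot(length(omega_grid) > 0, length(k_grid) > 0,
            length(drive_freqs) > 0)
  change <- array(NA_real_,
                  dim = c(length(omega_grid), length(k_grid),
                          length(drive_freqs)),
                  dimnames = list(omega = omega_grid, k = k_grid,
                                  drive = drive_freqs))
  # one undriven reference run per omega, shared across k and drives
  base <- vapply(omega_grid, function(om) {
    p0 <- oscillator_params(omega = om, k = 0)
    oscillation_amplitude(integrate_oscillator(p0, duration, dt_out),
                          p0$drive_onset + transient, duration)
  }, numeric(1))
  for (di in seq_along(drive_freqs)) {
    for (ki in seq_along(k_grid)) {
      if (k_grid[ki] == 0) {
        change[, ki, di] <- 0  # matched undriven runs: no change
        next
      }
      for (oi in seq_along(omega_grid)) {
        p <- oscillator_params(omega = omega_grid[oi], k = k_grid[ki],
                               drive_freq = drive_freqs[di])
        change[oi, ki, di] <- entrainment_change(p, duration, transient,
                                                 dt_out,
                                                 baseline = base[oi])
      }
    }
  }
  structure(list(omega_grid = omega_grid, k_grid = k_grid,
                 drive_freqs = drive_freqs, change = change),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("oscillator sweep: %d omega x %d k x %d drive frequencies (%d cells)\n",
              length(x$omega_grid), length(x$k_grid), length(x$drive_freqs),
              length(x$change)))
  invisible(x)
}

#' Individual resonance frequency by model-profile correlation
#'
#' Correlates a participant's empirical 4-point profile (normalized tACS
#' effect per drive frequency) with the model's entrainment-change profile
#' at every (omega, k) grid point, and returns the omega of the global
#' correlation maximum (Pearson). Ties are broken toward lower omega, then
#' lower k. Grid points with zero profile variance (e.g. k = 0) are skipped.
#'
#' @param empirical_profile Numeric vector, one value per drive frequency in
#'   `sweep$drive_freqs` order; must have nonzero variance.
#' @param sweep A `sweep_result`.
#' @return A `resonance_estimate`: `best_omega` (Hz), `best_k`,
#'   `correlation_profile` (max-over-k correlation per omega), `best_cor`.
#' @export
estimate_resonance <- function(empirical_profile, sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  nf <- length(sweep$drive_freqs)
  if (length(empirical_profile) != nf)
    stop("estimate_resonance: profile length must match drive frequencies")
  if (any(!is.finite(empirical_profile)))
    stop("estimate_resonance: non-finite profile")
  if (stats::sd(empirical_profile) == 0)
    stop("estimate_resonance: zero-variance profile, correlation undefined")
  no <- length(sweep$omega_grid)
  nk <- length(sweep$k_grid)
  cors <- matrix(NA_real_, no, nk)
  for (ki in seq_len(nk)) {
    m <- sweep$change[, ki, , drop = TRUE]  # omega x drive
    if (is.null(dim(m))) m <- matrix(m, nrow = no)
    v <- apply(m, 1, stats::sd)
    ok <- v > 0
    if (any(ok))
      cors[ok, ki] <- suppressWarnings(
        as.vector(stats::cor(t(m[ok, , drop = FALSE]), empirical_profile)))
  }
  if (all(is.na(cors)))
    stop("estimate_resonance: no grid point with profile variance")
  best <- which(cors == max(cors, na.rm = TRUE), arr.ind = TRUE)
  # lowest omega, then lowest k
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  structure(list(best_omega = sweep$omega_grid[best[1]],
                 best_k = sweep$k_grid[best[2]],
                 best_cor = cors[best[1], best[2]],
                 correlation_profile = apply(cors, 1, max, na.rm = TRUE),
                 omega_grid = sweep$omega_grid),
            class = "resonance_estimate")
}

#' @export
print.resonance_estimate <- function(x, ...) {
  cat(sprintf("resonance estimate: omega %.1f Hz (k = %.1f, r = %.3f)\n",
              x$best_omega, x$best_k, x$best_cor))
  invisible(x)
}

#' Hierarchical clustering of resonance frequencies
#'
#' Average-linkage agglomerative clustering on 1-D Euclidean distances
#' between participants' resonance frequencies.
#'
#' @param frequencies Resonance frequency (Hz) per participant (>= 2).
#' @param n_clusters Number of clusters at the cut (default 2).
#' @return List with `labels` (cluster id per participant), `means`
#'   (cluster mean frequency, ordered by cluster id), `hclust` (the tree).
#' @export
cluster_resonances <- function(frequencies, n_clusters = 2) {
  n <- length(frequencies)
  if (n < 2) stop("cluster_resonances: need >= 2 participants")
  if (n_clusters > n) stop("cluster_resonances: more clusters than points")
  hc <- stats::hclust(stats::dist(frequencies), method = "average")
  labels <- stats::cutree(hc, k = n_clusters)
  means <- vapply(split(frequencies, labels), mean, numeric(1))
  list(labels = labels, means = means, hclust = hc)
}
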