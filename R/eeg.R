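#' @keywords internal
.hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# one-sided frequency axis for an n-sample epoch
.freq_axis <- function(n, fs) (0:(floor(n / 2))) * fs / n

#' Evoked amplitude spectrum of an epoch set
#'
#' Averages epochs in the time domain (per channel), applies a Hann window,
#' and takes the modulus of the discrete Fourier transform. The amplitude
#' scale is compensated for the one-sided spectrum and the window's
#' coherent gain (`2 / sum(w)`), so a phase-locked unit-amplitude sinusoid
#' on a Fourier bin yields amplitude 1. Components that are phase-random
#' across trials average out before the transform, so this spectrum
#' isolates phase-locked (evoked) activity.
#'
#' @param epochs An `epoch_set` (see [simulate_eeg_epochs()]) with >= 2
#'   trials.
#' @return A `spectrum_result`: `freqs` (Hz), `amplitude` (channels x
#'   freqs matrix), `measure = "amplitude"`, plus the epoch metadata.
#' @export
evoked_spectrum <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] < 2) stop("evoked_spectrum: need >= 2 trials")
  n <- d[3]
  w <- .hann(n)
  avg <- apply(epochs$data, c(2, 3), mean)  # channels x samples
  nf <- floor(n / 2) + 1
  amp <- t(apply(avg, 1, function(x)
    2 * Mod(stats::fft(w * x))[seq_len(nf)] / sum(w)))
  dimnames(amp) <- list(epochs$channel_labels, NULL)
  structure(list(freqs = .freq_axis(n, epochs$fs), amplitude = amp,
                 measure = "amplitude", fs = epochs$fs,
                 condition = epochs$condition,
                 channel_labels = epochs$channel_labels),
            class = "spectrum_result")
}

#' Intertrial phase coherence spectrum
#'
#' Applies the Hann-windowed Fourier transform to every single trial,
#' extracts the phase angle per frequency and channel, and computes the
#' resultant vector length of the unit phasors across trials: 1 when every
#' trial has the same phase at that frequency, near 0 for random phases.
#' Invariant to per-trial amplitude scaling.
#'
#' @param epochs An `epoch_set`. A single trial gives R = 1 everywhere and
#'   raises a warning.
#' @return A `spectrum_result` with `vector_length` (channels x freqs) and
#'   `measure = "vector_length"`.
#' @export
itc_spectrum <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] < 2) warning("itc_spectrum: single trial, R = 1 is degenerate")
  n <- d[3]
  w <- .hann(n)
  nf <- floor(n / 2) + 1
  vl <- matrix(NA_real_, d[2], nf,
               dimnames = list(epochs$channel_labels, NULL))
  for (ch in seq_len(d[2])) {
    phasors <- matrix(0i, d[1], nf)
    for (tr in seq_len(d[1])) {
      X <- stats::fft(w * epochs$data[tr, ch, ])[seq_len(nf)]
      phasors[tr, ] <- exp(1i * Arg(X))
    }
    vl[ch, ] <- Mod(colMeans(phasors))
  }
  structure(list(freqs = .freq_axis(n, epochs$fs), vector_length = vl,
                 measure = "vector_length", fs = epochs$fs,
                 condition = epochs$condition,
                 channel_labels = epochs$channel_labels),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  cat(sprintf("spectrum (%s): %d channels, %d frequencies (0-%g Hz), condition %g Hz\n",
              x$measure, length(x$channel_labels), length(x$freqs),
              max(x$freqs), x$condition))
  invisible(x)
}

#' Average a spectrum over a channel cluster
#'
#' @param result A `spectrum_result`.
#' @param channel_subset Channel labels to average (must all exist);
#'   defaults to the fronto-central cluster.
#' @return Numeric vector, one value per frequency.
#' @export
cluster_average <- function(result, channel_subset = fronto_central_cluster()) {
  stopifnot(inherits(result, "spectrum_result"))
  missing_ch <- setdiff(channel_subset, result$channel_labels)
  if (length(missing_ch) > 0)
    stop("cluster_average: unknown channel(s) ",
         paste(missing_ch, collapse = ", "))
  m <- result[[if (result$measure == "amplitude") "amplitude"
               else "vector_length"]]
  colMeans(m[channel_subset, , drop = FALSE])
}

#' Read a spectrum value at a target frequency
#'
#' Returns the value at the Fourier bin nearest to `freq`; warns when the
#' target is off-grid by more than a tenth of the bin width.
#'
#' @param values Per-frequency vector (e.g. from [cluster_average()]).
#' @param freqs Frequency axis (Hz).
#' @param freq Target frequency (Hz).
#' @return Scalar value at the nearest bin.
#' @export
value_at_freq <- function(values, freqs, freq) {
  i <- which.min(abs(freqs - freq))
  off <- abs(freqs[i] - freq)
  res <- if (length(freqs) > 1) freqs[2] - freqs[1] else Inf
  if (off > res / 10)
    warning(sprintf("value_at_freq: %g Hz is off-grid; using nearest bin %g Hz",
                    freq, freqs[i]))
  values[i]
}

#' Cross-condition normalization of frequency-tagged responses
#'
#' For each stimulation rate `f`, divides the response measured at `f` when
#' the stimulus was presented at `f` by the mean response at `f` when the
#' stimulus was presented at every other rate. This controls for
#' frequency-dependent noise floors (1/f noise, per-bin estimation noise).
#' Values above 1 indicate a response specific to the matching condition.
#'
#' @param values Square matrix: rows = stimulus condition, columns =
#'   measured frequency, both in the same rate order (`rates`).
#' @param rates Rate labels (Hz) for rows/columns.
#' @return Named vector of normalized values, one per rate.
#' @export
normalize_across_conditions <- function(values, rates) {
  values <- as.matrix(values)
  k <- length(rates)
  if (!all(dim(values) == k))
    stop("normalize_across_conditions: need a ", k, "x", k, " matrix")
  out <- vapply(seq_len(k), function(i) {
    denom <- mean(values[-i, i])
    if (denom == 0) stop("normalize_across_conditions: zero denominator at ",
                         rates[i], " Hz")
    values[i, i] / denom
  }, numeric(1))
  stats::setNames(out, rates)
}

#' Preferred stimulation rate
#'
#' The rate with the highest normalized response; ties are broken toward
#' the lower rate (flagged via attribute `tie`).
#'
#' @param values Normalized values, one per rate.
#' @param rates Rates in Hz, same order.
#' @return The preferred rate (Hz), with attribute `tie` when ties occurred.
#' @export
preferred_rate <- function(values, rates) {
  if (any(is.na(values))) stop("preferred_rate: NA values")
  stopifnot(length(values) == length(rates))
  i <- which(values == max(values))
  out <- rates[min(i)]
  if (length(i) > 1) attr(out, "tie") <- TRUE
  out
}

#' Linear trend of entrainment across stimulation rates
#'
#' Ordinary least-squares fit of a response measure on stimulation rate
#' (pooling participants), with the standard F test against the
#' intercept-only model.
#'
#' @param y Response values (e.g. normalized vector length), one per
#'   participant x rate observation.
#' @param x Stimulation rate (Hz) for each observation; >= 3 distinct
#'   values required.
#' @return List with `slope`, `intercept`, `r_squared`, `F`, `p_value`,
#'   `df`, and the fitted `lm` object.
#' @export
linear_trend <- function(y, x) {
  if (length(unique(x)) < 3) stop("linear_trend: need >= 3 distinct rates")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       F = unname(s$fstatistic[1]),
       p_value = unname(stats::pf(s$fstatistic[1], s$fstatistic[2],
                                  s$fstatistic[3], lower.tail = FALSE)),
       df = unname(s$fstatistic[2:3]),
       model = fit)
}
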