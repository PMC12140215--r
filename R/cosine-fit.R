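#' Single-cycle cosine fit to phase-binned rates
#'
#' Least-squares fit of `offset + amplitude * cos(phi - phase)` to values
#' observed at a set of phase angles, via the linear sine/cosine basis
#' (`rate ~ 1 + cos(phi) + sin(phi)`), which has the same optimum as a
#' nonlinear fit of the amplitude/phase parameterization. The fitted
#' amplitude is the behavioral-entrainment measure used throughout the
#' package (entAmp); the fitted phase is the preferred phase (prefPhase).
#'
#' On equally spaced bins the basis is orthogonal, so noiseless cosine data
#' are recovered exactly.
#'
#' @param bin_centers Phase angles in radians (>= 3 distinct values).
#' @param rates Values at those angles (e.g., hit rates).
#' @return An object of class `cosine_fit`: `offset`, `amplitude` (>= 0),
#'   `phase` (radians in `[-pi, pi)`), `fitted`, `rss`, `degenerate`
#'   (TRUE when the response is flat so the phase is arbitrary).
#' @examples
#' b <- phase_binning(9)
#' y <- 0.5 + 0.2 * cos(b$centers - pi / 2)
#' f <- fit_cosine(b$centers, y)
#' c(f$offset, f$amplitude, f$phase)  # 0.5, 0.2, pi/2
#' @export
fit_cosine <- function(bin_centers, rates) {
  if (length(bin_centers) != length(rates))
    stop("fit_cosine: bin_centers and rates differ in length")
  if (length(unique(round(wrap_phase(bin_centers), 12))) < 3L)
    stop("fit_cosine: need at least 3 distinct phase angles")
  if (any(!is.finite(rates))) stop("fit_cosine: non-finite rates")
  X <- cbind(1, cos(bin_centers), sin(bin_centers))
  beta <- qr.coef(qr(X), rates)
  fitted <- drop(X %*% beta)
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  degenerate <- amp < 1e-12
  structure(list(
    offset = unname(beta[1]),
    amplitude = unname(amp),
    phase = if (degenerate) 0 else wrap_phase(atan2(beta[3], beta[2])),
    fitted = fitted,
    rss = sum((rates - fitted)^2),
    degenerate = degenerate
  ), class = "cosine_fit")
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf("cosine fit: offset %.4f, amplitude %.4f, phase %.3f rad%s\n",
              x$offset, x$amplitude, x$phase,
              if (x$degenerate) " (degenerate: flat response)" else ""))
  invisible(x)
}

#' Hit rate per phase bin
#'
#' Tabulates hits/total within each bin of a circular binning, the first
#' stage of every entrainment estimate in this package.
#'
#' @param table A trial table (data frame) with an `accuracy` column in
#'   `{0, 1}`.
#' @param binning A [phase_binning()] object.
#' @param phase_column Name of the phase column to bin on (e.g. `"fm_phase"`,
#'   `"tacs_phase"`).
#' @param require_all_bins Error when a bin receives no trials (default TRUE,
#'   mirroring the exclusion of participants with empty phase-by-condition
#'   cells).
#' @return Data frame with `bin`, `center`, `n`, `hits`, `rate`.
#' @export
binned_hit_rates <- function(table, binning, phase_column = "fm_phase",
                             require_all_bins = TRUE) {
  stopifnot(is.data.frame(table), inherits(binning, "phase_binning"))
  if (!phase_column %in% names(table))
    stop("binned_hit_rates: no column '", phase_column, "'")
  acc <- table$accuracy
  if (any(is.na(acc)) || !all(acc %in% c(0, 1)))
    stop("binned_hit_rates: accuracy must be 0/1 with no NA")
  idx <- bin_phase(table[[phase_column]], binning)
  n <- tabulate(idx, nbins = binning$n_bins)
  hits <- vapply(seq_len(binning$n_bins),
                 function(b) sum(acc[idx == b]), numeric(1))
  if (require_all_bins && any(n == 0L))
    stop("binned_hit_rates: empty phase bin(s) ",
         paste(which(n == 0L), collapse = ", "),
         " for column '", phase_column, "'")
  data.frame(bin = seq_len(binning$n_bins), center = binning$centers,
             n = n, hits = hits, rate = ifelse(n > 0, hits / n, NA_real_))
}

#' Entrainment amplitude of a trial table
#'
#' Convenience composition: bin hit rates on a phase column and fit a cosine.
#'
#' @inheritParams binned_hit_rates
#' @return A `cosine_fit`.
#' @export
entrainment_fit <- function(table, binning, phase_column = "fm_phase") {
  br <- binned_hit_rates(table, binning, phase_column)
  fit_cosine(br$center, br$rate)
}

#' Permutation surrogate null distribution
#'
#' Builds the null distribution of a statistic by shuffling single-trial
#' accuracy values across a participant's trials while keeping all phase/
#' condition labels fixed, and recomputing the statistic on each surrogate
#' table. The default statistic is the cosine-fit entrainment amplitude on
#' `phase_column`, for which a closed-form vectorized path is used.
#'
#' @param table Trial table for one shuffling unit (typically one
#'   participant x session x condition).
#' @param binning A [phase_binning()].
#' @param phase_column Phase column the statistic is computed on.
#' @param statistic_fn Optional function `f(table) -> scalar`; when NULL the
#'   entrainment amplitude is used.
#' @param n_perm Number of surrogates (default 1000).
#' @param seed Integer seed; the permutation stream is fully determined by it.
#' @return Object of class `surrogate_null`: `values` (length `n_perm`),
#'   `mean`, `sd`, and `quantile(p)` accessor via [stats::quantile()].
#' @export
surrogate_null <- function(table, binning, phase_column = "fm_phase",
                           statistic_fn = NULL, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  acc <- table$accuracy
  if (any(is.na(acc))) stop("surrogate_null: NA accuracy")
  set.seed(as.integer(seed))
  if (is.null(statistic_fn)) {
    # vectorized amplitude path: permuted bin-wise hit counts + linear basis
    idx <- bin_phase(table[[phase_column]], binning)
    n_bin <- tabulate(idx, nbins = binning$n_bins)
    if (any(n_bin == 0L)) stop("surrogate_null: empty phase bin")
    X <- cbind(1, cos(binning$centers), sin(binning$centers))
    # coefficient extractor for the cos/sin columns
    H <- solve(crossprod(X), t(X))[2:3, , drop = FALSE]
    vals <- vapply(seq_len(n_perm), function(i) {
      a <- acc[sample.int(length(acc))]
      rate <- vapply(seq_len(binning$n_bins),
                     function(b) sum(a[idx == b]), numeric(1)) / n_bin
      b2 <- H %*% rate
      sqrt(sum(b2^2))
    }, numeric(1))
  } else {
    vals <- vapply(seq_len(n_perm), function(i) {
      tb <- table
      tb$accuracy <- acc[sample.int(length(acc))]
      statistic_fn(tb)
    }, numeric(1))
  }
  structure(list(values = vals, n_perm = n_perm,
                 mean = mean(vals), sd = stats::sd(vals)),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf("surrogate null: %d permutations, mean %.4f, sd %.4f\n",
              x$n_perm, x$mean, x$sd))
  invisible(x)
}

#' z-score an observed statistic against its surrogate null
#'
#' @param observed Observed scalar statistic.
#' @param null A `surrogate_null`.
#' @return `(observed - mean) / sd` of the null.
#' @export
zscore_vs_null <- function(observed, null) {
  stopifnot(inherits(null, "surrogate_null"))
  if (!is.finite(null$sd) || null$sd <= 0)
    stop("zscore_vs_null: degenerate null (sd = 0); cannot z-score")
  (observed - null$mean) / null$sd
}

#' One-sided surrogate significance at the 95th percentile
#'
#' A participant's entrainment is deemed significant when the observed
#' statistic exceeds the 95th percentile of its surrogate distribution.
#'
#' @inheritParams zscore_vs_null
#' @param level Percentile (default 0.95).
#' @return Logical.
#' @export
exceeds_null <- function(observed, null, level = 0.95) {
  stopifnot(inherits(null, "surrogate_null"))
  observed > stats::quantile(null$values, level, names = FALSE, type = 7)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles is uniformly distributed on the circle.
#' `R` is the resultant vector length, `z = n * R^2`, and the p-value uses
#' the standard small-sample series correction (Zar's approximation).
#'
#' @param angles Angles in radians, `n >= 2`, no NA.
#' @return List with `R`, `z`, `p_value`, `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2L) stop("rayleigh_test: need at least 2 angles")
  if (any(is.na(angles))) stop("rayleigh_test: NA angles")
  R <- resultant_length(angles)
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                    (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  list(R = R, z = z, p_value = max(min(p, 1), 0), n = n)
}
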