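#' Wrap phase angles to \[-pi, pi)
#'
#' Maps any finite angle onto the principal interval `[-pi, pi)` (half-open:
#' `-pi` is representable, `+pi` wraps to `-pi`). The operation is idempotent
#' and preserves the angle modulo `2*pi`.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector of the same length, in `[-pi, pi)`.
#' @examples
#' wrap_phase(3 * pi / 2)   # -pi/2
#' wrap_phase(-pi)          # -pi (boundary stays)
#' @export
wrap_phase <- function(x) {
  if (any(!is.finite(x))) stop("wrap_phase: non-finite angles")
  ((x + pi) %% (2 * pi)) - pi
}

#' Equally spaced circular phase binning
#'
#' Constructs `n_bins` half-open bins `[center - pi/n, center + pi/n)` whose
#' centers sit at `2*pi*j/n_bins` (wrapped), so that one center is exactly at
#' phase zero. The bins partition `[-pi, pi)`: every wrapped phase maps to
#' exactly one bin.
#'
#' @param n_bins Number of bins (>= 2).
#' @return An object of class `phase_binning` with elements `n_bins`,
#'   `centers` (radians, in bin-index order starting at 0) and `half_width`.
#' @examples
#' b <- phase_binning(9)
#' b$centers  # 2*pi*j/9 wrapped to [-pi, pi)
#' @export
phase_binning <- function(n_bins) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2) stop("phase_binning: n_bins must be >= 2")
  centers <- wrap_phase(2 * pi * (seq_len(n_bins) - 1) / n_bins)
  structure(list(n_bins = n_bins, centers = centers,
                 half_width = pi / n_bins),
            class = "phase_binning")
}

#' Assign phases to bins
#'
#' @param phase Numeric vector of angles (any real values; wrapped first).
#' @param binning A [phase_binning()] object.
#' @return Integer bin indices in `1..n_bins`; index `i` has center
#'   `binning$centers[i]`.
#' @export
bin_phase <- function(phase, binning) {
  stopifnot(inherits(binning, "phase_binning"))
  n <- binning$n_bins
  ph <- wrap_phase(phase)
  # shift by half a bin so that floor() buckets around each center
  idx <- floor((ph + binning$half_width) %% (2 * pi) / (2 * pi) * n)
  as.integer(idx %% n) + 1L
}

#' @export
print.phase_binning <- function(x, ...) {
  cat(sprintf("phase binning: %d half-open bins of width %.1f deg, centers at 2*pi*j/%d\n",
              x$n_bins, 360 / x$n_bins, x$n_bins))
  invisible(x)
}

#' Circular resultant vector length
#'
#' Length of the mean unit phasor of a set of angles; 1 when all angles agree,
#' near 0 for dispersed angles.
#'
#' @param angles Numeric vector of angles in radians (no NA).
#' @return Scalar in `[0, 1]`.
#' @keywords internal
resultant_length <- function(angles) {
  if (length(angles) == 0L) stop("resultant_length: empty input")
  if (any(is.na(angles))) stop("resultant_length: NA angles")
  Mod(mean(exp(1i * angles)))
}
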