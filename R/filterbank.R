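#' ERB scale helpers
#'
#' Equivalent rectangular bandwidth of the auditory filter at centre
#' frequency `f_hz`, and the ERB-number (ERB-rate) scale, after Glasberg &
#' Moore: `ERB(f) = 24.7 (4.37 f/1000 + 1)`,
#' `ERBn(f) = 21.4 log10(4.37 f/1000 + 1)`.
#'
#' @param f_hz Frequency in Hz (vectorised).
#' @return Bandwidth in Hz / ERB number / frequency in Hz respectively.
#' @export
erb_bandwidth <- function(f_hz) 24.7 * (4.37 * f_hz / 1000 + 1)

#' @rdname erb_bandwidth
#' @export
erb_number <- function(f_hz) 21.4 * log10(4.37 * f_hz / 1000 + 1)

#' @rdname erb_bandwidth
#' @param n ERB number.
#' @export
erb_to_hz <- function(n) (10^(n / 21.4) - 1) * 1000 / 4.37

#' Design a gammatone filterbank
#'
#' Fourth-order gammatone filters with centre frequencies spaced
#' `1/erb_density` ERB apart between `f_lo_hz` and `f_hi_hz` (the highest
#' centre never exceeds `f_hi_hz`).
#'
#' @param sample_rate_hz Sampling rate the bank will operate at.
#' @param f_lo_hz,f_hi_hz Band edges in Hz.
#' @param erb_density Filters per ERB (default 1).
#' @return An object of class `filterbank_spec` with fields
#'   `center_freqs_hz`, `bandwidths_hz`, `sample_rate_hz`, `order`.
#' @export
design_filterbank <- function(sample_rate_hz, f_lo_hz, f_hi_hz,
                              erb_density = 1) {
  if (f_lo_hz > f_hi_hz) stop("design_filterbank: f_lo_hz must be <= f_hi_hz")
  if (f_hi_hz > sample_rate_hz / 2)
    stop("design_filterbank: f_hi_hz exceeds the Nyquist frequency")
  n_lo <- erb_number(f_lo_hz)
  n_hi <- erb_number(f_hi_hz)
  ns <- seq(n_lo, n_hi, by = 1 / erb_density)
  cfs <- erb_to_hz(ns)
  structure(list(center_freqs_hz = cfs,
                 bandwidths_hz = erb_bandwidth(cfs),
                 sample_rate_hz = sample_rate_hz,
                 f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
                 erb_density = erb_density,
                 order = 4L),
            class = "filterbank_spec")
}

#' @export
print.filterbank_spec <- function(x, ...) {
  cat(sprintf("gammatone filterbank: %d channels, %.0f-%.0f Hz @ %g Hz\n",
              length(x$center_freqs_hz), min(x$center_freqs_hz),
              max(x$center_freqs_hz), x$sample_rate_hz))
  invisible(x)
}

# Frequency response of a 4th-order gammatone filter, evaluated on an FFT
# grid.  H(f) = [1 + i (f - fc)/b']^-4 with b' = 1.019 * ERB(fc), applied
# conjugate-symmetrically so time-domain output is real.
gammatone_response <- function(freqs, fc, n, fs) {
  b <- 1.019 * erb_bandwidth(fc)
  # fold FFT bin frequencies to [-fs/2, fs/2)
  f <- ifelse(freqs > fs / 2, freqs - fs, freqs)
  hp <- (1 + 1i * (abs(f) - fc) / b)^-4
  # conjugate for negative frequencies
  ifelse(f < 0, Conj(hp), hp)
}

#' Gammatone filterbank, half-wave rectification and envelope extraction
#'
#' Applies the filterbank in the Fourier domain (linear-phase-free exact
#' gammatone magnitude/phase response), then per channel half-wave
#' rectifies and lowpass-filters at `env_lp_hz` (first order) to extract
#' the envelope, the standard haircell stage of the perception model.
#'
#' @param signal An [audio_signal()] at the bank's sampling rate.
#' @param fb A [design_filterbank()] spec.
#' @param env_lp_hz Envelope lowpass cutoff (Hz).
#' @return A numeric matrix, time samples x channels, nonnegative.
#' @export
peripheral_and_envelope <- function(signal, fb, env_lp_hz = 1000) {
  if (signal$sample_rate_hz != fb$sample_rate_hz)
    stop("peripheral_and_envelope: signal rate differs from filterbank rate")
  x <- signal$samples
  n <- length(x)
  fs <- fb$sample_rate_hz
  X <- stats::fft(x)
  freqs <- (0:(n - 1L)) * fs / n
  cfs <- fb$center_freqs_hz
  env <- matrix(0, n, length(cfs))
  a <- exp(-2 * pi * env_lp_hz / fs)
  for (c in seq_along(cfs)) {
    H <- gammatone_response(freqs, cfs[c], n, fs)
    y <- Re(stats::fft(X * H, inverse = TRUE)) / n
    y[y < 0] <- 0
    env[, c] <- as.numeric(stats::filter((1 - a) * y, a, method = "recursive"))
  }
  env
}
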