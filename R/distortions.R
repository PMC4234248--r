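#' Nonlinear frequency compression settings
#'
#' Holds the knee point `cutoff_hz` (F_c) and the compression ratio
#' `compression_ratio` (CR = 1/p, p the compression exponent).  CR = 1 is
#' the identity map.
#'
#' @param cutoff_hz Cutoff (knee) frequency F_c in Hz, > 0.
#' @param compression_ratio CR >= 1.
#' @return An object of class `nfc_settings`.
#' @export
nfc_settings <- function(cutoff_hz, compression_ratio) {
  if (cutoff_hz <= 0) stop("nfc_settings: cutoff_hz must be > 0")
  if (compression_ratio < 1) stop("nfc_settings: compression_ratio must be >= 1")
  structure(list(cutoff_hz = as.numeric(cutoff_hz),
                 compression_ratio = as.numeric(compression_ratio)),
            class = "nfc_settings")
}

#' The five standard NFC study settings
#'
#' Cutoff/CR pairs spanning mild to strong compression:
#' (4000 Hz, 2:1), (3000 Hz, 2:1), (3000 Hz, 6:1), (3000 Hz, 10:1),
#' (2000 Hz, 2:1), labelled `cr2-fc4k`, `cr2-fc3k`, `cr6-fc3k`,
#' `cr10-fc3k`, `cr2-fc2k`.
#'
#' @return Named list of [nfc_settings()].
#' @export
standard_nfc_settings <- function() {
  list(`cr2-fc4k`  = nfc_settings(4000, 2),
       `cr2-fc3k`  = nfc_settings(3000, 2),
       `cr6-fc3k`  = nfc_settings(3000, 6),
       `cr10-fc3k` = nfc_settings(3000, 10),
       `cr2-fc2k`  = nfc_settings(2000, 2))
}

#' NFC input/output frequency map
#'
#' Below the knee the map is the identity; above it frequencies are
#' compressed along a line in log-frequency:
#' \deqn{F_{out} = F_c^{1-p} F_{in}^p, \quad p = 1/CR.}
#' The map is continuous and non-decreasing.  With `piecewise_linear =
#' TRUE` an alternative linear map `F_out = F_c + (F_in - F_c)/CR` is used
#' for sensitivity checks.
#'
#' @param f_in_hz Input frequency (vectorised), >= 0.
#' @param settings An [nfc_settings()].
#' @param piecewise_linear Use the linear-above-knee variant.
#' @return Output frequency in Hz.
#' @export
map_frequency <- function(f_in_hz, settings, piecewise_linear = FALSE) {
  if (any(f_in_hz < 0)) stop("map_frequency: frequencies must be >= 0")
  fc <- settings$cutoff_hz
  p <- 1 / settings$compression_ratio
  out <- f_in_hz
  hi <- f_in_hz > fc
  if (any(hi)) {
    out[hi] <- if (piecewise_linear) fc + (f_in_hz[hi] - fc) * p
               else fc^(1 - p) * f_in_hz[hi]^p
  }
  out
}

#' Apply nonlinear frequency compression to a signal
#'
#' Short-time Fourier realisation: each analysis frame's spectrum is
#' remapped so that the energy at frequency f moves to
#' [map_frequency()](f), with linear interpolation between target bins and
#' the phase carried over from the source bin.  Content below the knee is
#' untouched (the map is the identity there).
#'
#' @param signal An [audio_signal()].
#' @param settings An [nfc_settings()]; `cutoff_hz` must lie below Nyquist.
#' @param frame_len Analysis frame length in samples (power of two).
#' @param hop Hop size in samples.
#' @param piecewise_linear Passed to [map_frequency()].
#' @return The processed [audio_signal()].
#' @export
nfc_process <- function(signal, settings, frame_len = 1024, hop = 256,
                        piecewise_linear = FALSE) {
  fs <- signal$sample_rate_hz
  if (settings$cutoff_hz >= fs / 2)
    stop("nfc_process: cutoff_hz must be below the Nyquist frequency")
  x <- signal$samples
  n <- length(x)
  win <- hann_window(frame_len)
  nbins <- frame_len %/% 2L + 1L
  freqs <- (0:(nbins - 1L)) * fs / frame_len
  fmap <- map_frequency(freqs, settings, piecewise_linear)
  # target bin (fractional) for every source bin
  tpos <- fmap / (fs / frame_len)
  lo <- pmin(floor(tpos), nbins - 1)
  whi <- tpos - lo
  lo <- as.integer(lo) + 1L              # 1-based lower target bin
  hi_b <- pmin(lo + 1L, nbins)
  identical_map <- all(abs(fmap - freqs) < 1e-9)

  nframes <- max(1L, 1L + ceiling((n - frame_len) / hop))
  npad <- (nframes - 1L) * hop + frame_len
  x <- c(x, numeric(npad - n))
  y <- numeric(npad)
  wsum <- numeric(npad)
  # phase propagation: rotate each relocated bin so that its phase advances
  # across frames at the *target* frequency, keeping overlap-add coherent
  rot_step <- exp(1i * 2 * pi * (fmap - freqs) * hop / fs)
  for (j in seq_len(nframes)) {
    idx <- ((j - 1L) * hop + 1L):((j - 1L) * hop + frame_len)
    X <- stats::fft(x[idx] * win)
    Xh <- X[1:nbins]
    if (identical_map) {
      Yh <- Xh
    } else {
      Xh <- Xh * rot_step^(j - 1L)
      re <- numeric(nbins); im <- numeric(nbins)
      a <- (1 - whi) * Re(Xh); b <- (1 - whi) * Im(Xh)
      re <- re + unname(tapply_add(a, lo, nbins))
      im <- im + unname(tapply_add(b, lo, nbins))
      a <- whi * Re(Xh); b <- whi * Im(Xh)
      re <- re + unname(tapply_add(a, hi_b, nbins))
      im <- im + unname(tapply_add(b, hi_b, nbins))
      Yh <- complex(real = re, imaginary = im)
    }
    Yfull <- c(Yh, Conj(Yh[(nbins - 1L):2L]))
    yf <- Re(stats::fft(Yfull, inverse = TRUE)) / frame_len
    y[idx] <- y[idx] + yf * win
    wsum[idx] <- wsum[idx] + win^2
  }
  ok <- wsum > 1e-8
  y[ok] <- y[ok] / wsum[ok]
  y <- y[1:n]
  if (!identical_map) {
    # the map places no content above map(Nyquist): remove overlap-add
    # splatter beyond it
    f_top <- map_frequency(fs / 2, settings, piecewise_linear) + fs / frame_len
    Y <- stats::fft(y)
    bins <- (0:(n - 1L)) * fs / n
    kill <- bins > f_top & bins < fs - f_top
    Y[kill] <- 0
    y <- Re(stats::fft(Y, inverse = TRUE)) / n
  }
  audio_signal(y, fs, spl_reference_db = signal$spl_reference_db)
}

# sum 'values' into an accumulator of length n at integer positions 'at'
tapply_add <- function(values, at, n) {
  out <- numeric(n)
  s <- rowsum(values, at)
  out[as.integer(rownames(s))] <- s
  out
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)
}

#' Lowpass anchor degradation
#'
#' Butterworth lowpass of the stated order (single pass, so the response is
#' -3 dB at the cutoff), as used for the low-quality anchor in MUSHRA
#' comparisons of frequency-lowered speech.
#'
#' @param signal An [audio_signal()].
#' @param order Filter order.
#' @param fc_hz Cutoff frequency in Hz (below Nyquist).
#' @return The filtered [audio_signal()].
#' @export
lowpass_anchor <- function(signal, order = 10, fc_hz = 2000) {
  fs <- signal$sample_rate_hz
  if (fc_hz >= fs / 2) stop("lowpass_anchor: cutoff must be below Nyquist")
  bt <- signal::butter(order, fc_hz / (fs / 2))
  y <- as.numeric(signal::filter(bt, signal$samples))
  audio_signal(y, fs, spl_reference_db = signal$spl_reference_db)
}

#' Peak-clipping anchor degradation
#'
#' Hard-clips the waveform at `fraction` of its own observed peak value;
#' samples within the bound are unchanged.
#'
#' @param signal An [audio_signal()].
#' @param fraction Clipping point as a fraction of the peak, in (0, 1].
#' @return The clipped [audio_signal()].
#' @export
clip_anchor <- function(signal, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1)
    stop("clip_anchor: fraction must be in (0, 1]")
  pk <- max(abs(signal$samples))
  if (pk == 0) stop("clip_anchor: silent input")
  thr <- fraction * pk
  signal$samples <- pmax(pmin(signal$samples, thr), -thr)
  signal
}
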