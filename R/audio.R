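#' Audio signal container
#'
#' Wraps a mono waveform together with its sampling rate and the SPL
#' calibration convention used throughout the package: a full-scale RMS of
#' 1.0 corresponds to `spl_reference_db` dB SPL (100 dB by default).
#'
#' @param samples Numeric vector of amplitudes, nominally within ±1.
#' @param sample_rate_hz Sampling rate in Hz (> 0).
#' @param spl_reference_db dB SPL assigned to a signal with RMS 1.
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate_hz, spl_reference_db = 100) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("audio_signal: 'samples' must be non-empty")
  if (!all(is.finite(samples)))
    stop("audio_signal: all samples must be finite")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      sample_rate_hz <= 0)
    stop("audio_signal: 'sample_rate_hz' must be a positive scalar")
  structure(
    list(samples = samples,
         sample_rate_hz = as.numeric(sample_rate_hz),
         spl_reference_db = as.numeric(spl_reference_db)),
    class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal: %d samples @ %g Hz (%.3f s), RMS %.4g (%.1f dB SPL)\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz,
              signal_rms(x), signal_level_db(x)))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param signal An `audio_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(signal) {
  length(signal$samples) / signal$sample_rate_hz
}

#' Root-mean-square amplitude
#' @param signal An `audio_signal`.
#' @return RMS of the samples (full scale = 1).
#' @export
signal_rms <- function(signal) {
  sqrt(mean(signal$samples^2))
}

#' Signal level in dB SPL under the calibration convention
#' @param signal An `audio_signal`.
#' @return Level in dB SPL (RMS 1 maps to `spl_reference_db`).
#' @export
signal_level_db <- function(signal) {
  r <- signal_rms(signal)
  if (r == 0) return(-Inf)
  signal$spl_reference_db + 20 * log10(r)
}

#' Scale a signal to a target presentation level
#' @param signal An `audio_signal`.
#' @param level_db Target level in dB SPL.
#' @return The rescaled `audio_signal`.
#' @export
set_level <- function(signal, level_db) {
  r <- signal_rms(signal)
  if (r == 0) stop("set_level: cannot scale a silent signal")
  target_rms <- 10^((level_db - signal$spl_reference_db) / 20)
  signal$samples <- signal$samples * (target_rms / r)
  signal
}

# ---------------------------------------------------------------------------
# WAV I/O (RIFF PCM 16/24/32-bit and IEEE float).  Written against the RIFF
# byte layout directly since no WAV codec is otherwise available to the
# package; scope is limited to canonical little-endian mono/stereo files.
# ---------------------------------------------------------------------------

#' Read a WAV file
#'
#' Reads RIFF/WAVE PCM (16/24/32-bit) or IEEE float (32/64-bit) files.
#' Multichannel files are reduced to the first (left) channel with a
#' warning.  Integer samples are scaled to ±1 full scale by the convention
#' `x / 2^(bits-1)`.
#'
#' @param path Path to the file.
#' @param spl_reference_db Calibration convention passed to [audio_signal()].
#' @return An [audio_signal()].
#' @export
read_wav <- function(path, spl_reference_db = 100) {
  if (!file.exists(path))
    stop(sprintf("read_wav: file does not exist: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop(sprintf("read_wav: not a RIFF file: %s", path))
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop(sprintf("read_wav: not a WAVE file: %s", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels = readBin(fmt_raw[3:4], "integer", 1, size = 2,
                             endian = "little", signed = FALSE),
        sample_rate = readBin(fmt_raw[5:8], "integer", 1, size = 4,
                              endian = "little"),
        bits = readBin(fmt_raw[15:16], "integer", 1, size = 2,
                       endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw) || length(data_raw) == 0L)
    stop(sprintf("read_wav: missing fmt/data chunk or empty file: %s", path))

  bits <- fmt$bits
  nch <- fmt$n_channels
  if (fmt$audio_format == 1L) {            # integer PCM
    if (bits == 16L) {
      x <- readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
                   endian = "little") / 32768
    } else if (bits == 24L) {
      n <- length(data_raw) %/% 3L
      m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388608
    } else if (bits == 32L) {
      x <- readBin(data_raw, "integer", length(data_raw) / 4L, size = 4,
                   endian = "little") / 2147483648
    } else {
      stop(sprintf("read_wav: unsupported PCM bit depth %d", bits))
    }
  } else if (fmt$audio_format == 3L) {     # IEEE float
    x <- readBin(data_raw, "double", length(data_raw) %/% (bits %/% 8L),
                 size = bits %/% 8L, endian = "little")
  } else {
    stop(sprintf("read_wav: unsupported audio format tag %d", fmt$audio_format))
  }
  if (nch > 1L) {
    warning(sprintf("read_wav: %d channels in %s; using the first channel",
                    nch, path))
    x <- x[seq(1L, length(x), by = nch)]
  }
  audio_signal(x, fmt$sample_rate, spl_reference_db = spl_reference_db)
}

#' Write a WAV file
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bits Bit depth: 16/24/32 (integer PCM) or "float" (32-bit IEEE).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16) {
  x <- signal$samples
  fs <- round(signal$sample_rate_hz)
  if (identical(bits, "float")) {
    fmt_tag <- 3L; nbits <- 32L
    payload <- writeBin(as.numeric(x), raw(), size = 4, endian = "little")
  } else {
    fmt_tag <- 1L; nbits <- as.integer(bits)
    full <- 2^(nbits - 1)
    # clamp to the representable range (R integers are 32-bit signed, so
    # -2^31 itself is not representable for 32-bit PCM)
    lo_clip <- if (nbits == 32L) -full + 1 else -full
    v <- as.integer(pmax(pmin(round(x * full), full - 1), lo_clip))
    if (nbits == 16L) {
      payload <- writeBin(v, raw(), size = 2, endian = "little")
    } else if (nbits == 32L) {
      payload <- writeBin(v, raw(), size = 4, endian = "little")
    } else if (nbits == 24L) {
      u <- ifelse(v < 0, v + 16777216, v)
      m <- rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)
      payload <- as.raw(as.integer(m))
    } else stop("write_wav: unsupported bit depth")
  }
  block_align <- nbits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + length(payload)), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(nbits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  writeBin(payload, con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Resampling and alignment
# ---------------------------------------------------------------------------

#' Band-limited resampling
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) and inverse-transformed at the new length, so
#' the result is exactly band-limited to the new Nyquist frequency and the
#' duration is preserved within one sample period.
#'
#' @param signal An [audio_signal()].
#' @param target_rate_hz New sampling rate (> 0).
#' @return The resampled [audio_signal()].
#' @export
resample_signal <- function(signal, target_rate_hz) {
  if (target_rate_hz <= 0) stop("resample_signal: target rate must be > 0")
  if (target_rate_hz == signal$sample_rate_hz) return(signal)
  x <- signal$samples
  n <- length(x)
  m <- max(2L, as.integer(round(n * target_rate_hz / signal$sample_rate_hz)))
  X <- stats::fft(x)
  Y <- complex(m)
  # keep the conjugate-symmetric low-frequency block
  keep <- min(n, m)
  h <- keep %/% 2L
  Y[1:(h + 1L)] <- X[1:(h + 1L)]
  if (h > 0L) Y[(m - h + 1L):m] <- X[(n - h + 1L):n]
  if (keep %% 2L == 0L && h > 0L) {
    # split the shared Nyquist bin to keep the output real-valued
    Y[h + 1L] <- Y[h + 1L] / 2
    Y[m - h + 1L] <- Y[m - h + 1L] + Y[h + 1L]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / n
  audio_signal(y, target_rate_hz, spl_reference_db = signal$spl_reference_db)
}

#' Time-align and level-match a test signal against a reference
#'
#' Finds the broadband cross-correlation lag (bounded to ±`max_lag_s`,
#' ties broken toward the smaller |lag|), shifts the test signal by it,
#' rescales the test RMS to the reference RMS, and truncates both to the
#' common length.
#'
#' @param test,ref `audio_signal`s at equal sampling rates.
#' @param max_lag_s Lag search bound in seconds.
#' @return A list with elements `test`, `ref`, `lag_samples`, `scale`.
#' @export
align_and_scale <- function(test, ref, max_lag_s = 0.5) {
  if (test$sample_rate_hz != ref$sample_rate_hz)
    stop("align_and_scale: sample rates differ")
  x <- test$samples; r <- ref$samples
  if (all(x == 0) || all(r == 0))
    stop("align_and_scale: zero-energy input")
  fs <- ref$sample_rate_hz
  maxlag <- min(as.integer(round(max_lag_s * fs)),
                length(x) - 1L, length(r) - 1L)
  # FFT cross-correlation
  nfft <- stats::nextn(length(x) + length(r) - 1L, 2)
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  R <- stats::fft(c(r, numeric(nfft - length(r))))
  cc <- Re(stats::fft(Conj(X) * R, inverse = TRUE)) / nfft
  # cc[k+1] = correlation at lag k (test delayed by k relative to ref),
  # wrap-around tail holds negative lags
  lags <- c(0:maxlag, -(maxlag:1))
  vals <- cc[c(1:(maxlag + 1L), nfft - (maxlag:1) + 1L)]
  best <- max(vals)
  cand <- lags[vals >= best - 1e-12 * abs(best)]
  k <- cand[which.min(abs(cand))]
  d <- -k   # d > 0: test is delayed by d samples relative to ref
  if (d > 0) {
    x <- x[-(1:d)]
  } else if (d < 0) {
    x <- c(numeric(-d), x)
  }
  n <- min(length(x), length(r))
  x <- x[1:n]; r2 <- r[1:n]
  sc <- sqrt(mean(r2^2) / mean(x^2))
  list(test = audio_signal(x * sc, fs, test$spl_reference_db),
       ref = audio_signal(r2, fs, ref$spl_reference_db),
       lag_samples = d,
       scale = sc)
}
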