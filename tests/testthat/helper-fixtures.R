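# Shared fixtures, generated once per test run.

.fix <- new.env(parent = emptyenv())

# short speech-like signal at the working rate (cached)
speech_fixture <- function(seed = 3, duration_s = 0.8) {
  key <- sprintf("sp_%d_%g", seed, duration_s)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- make_speechlike(fixture_spec(seed = seed,
                                                duration_s = duration_s))
  .fix[[key]]
}

tone_signal <- function(freq_hz, fs = 22050, duration_s = 1, amp = 0.5) {
  t <- (0:(round(duration_s * fs) - 1)) / fs
  audio_signal(amp * sin(2 * pi * freq_hz * t), fs)
}

# steady-state RMS of a filtered tone, discarding the onset transient
tail_rms <- function(x, discard = 0.2) {
  n <- length(x)
  sqrt(mean(x[ceiling(n * discard):n]^2))
}

# dominant spectral frequency (Hz) via plain periodogram peak
peak_freq <- function(signal, f_lo = 50) {
  n <- length(signal$samples)
  sp <- Mod(stats::fft(signal$samples))[1:(n %/% 2)]
  freqs <- (0:(n %/% 2 - 1)) * signal$sample_rate_hz / n
  sp[freqs < f_lo] <- 0
  freqs[which.max(sp)]
}
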