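#' Adaptation (compression) stage
#'
#' Five cascaded divisive feedback loops with time constants 5, 50, 129,
#' 253 and 500 ms.  Stationary inputs are compressed approximately
#' logarithmically (steady-state response `x^(1/32)`), onsets overshoot.
#' The input envelope is floored at the absolute-threshold amplitude
#' `floor_amp` (1e-5 of full scale, i.e. 0 dB SPL under the 100-dB
#' convention) before the loops, and the output is rescaled to model units
#' so that the resting (silence) output is 0 and a stationary full-scale
#' input maps to 100.
#'
#' @param envelopes Nonnegative matrix (time x channels).
#' @param sample_rate_hz Sampling rate of the envelope signal.
#' @param tau_s Loop time constants in seconds.
#' @param floor_amp Absolute-threshold floor in full-scale amplitude.
#' @param overshoot_limit Per-loop overshoot bound (broken-stick limiter):
#'   loop outputs above the stationary full-scale response are compressed
#'   to at most this factor of it; `<= 1` disables limiting.
#' @return Matrix (time x channels) in model units.
#' @export
adaptation_stage <- function(envelopes, sample_rate_hz,
                             tau_s = c(0.005, 0.05, 0.129, 0.253, 0.5),
                             floor_amp = 1e-5, overshoot_limit = 10) {
  if (any(envelopes < 0))
    stop("adaptation_stage: input must be nonnegative")
  y <- .adaptation_loops_cpp(envelopes, sample_rate_hz, tau_s, floor_amp,
                             overshoot_limit)
  rest <- floor_amp^(2^-length(tau_s))
  (y - rest) / (1 - rest) * 100
}

# Modulation filterbank layout: an ~2.5 Hz lowpass band plus bandpass
# bands at 5 and 10 Hz (5 Hz wide) and constant-Q (Q = 2) bands up to
# ~129 Hz.
modulation_bands <- function() {
  centers <- c(0, 5, 10, 10 * (5 / 3)^(1:5))   # 16.7, 27.8, 46.3, 77.2, 128.6
  bw <- c(2.5, 5, 5, centers[-(1:3)] / 2)      # constant Q = 2 above 10 Hz
  data.frame(center_hz = centers, bandwidth_hz = bw)
}

# First-order complex one-pole bandpass applied in the Fourier domain to
# the positive-frequency (analytic) part of x; returns the complex band
# signal.  For center 0 a real first-order lowpass response is used.
mod_filter_apply <- function(X, freqs, fs, center, bw) {
  if (center == 0) {
    f <- ifelse(freqs > fs / 2, freqs - fs, freqs)
    H <- 1 / (1 + 1i * f / bw)
    return(stats::fft(X * H, inverse = TRUE) / length(X))
  }
  f <- ifelse(freqs > fs / 2, freqs - fs, freqs)
  H <- complex(length(X))
  pos <- f >= 0
  H[pos] <- 2 / (1 + 1i * (f[pos] - center) / (bw / 2))
  H[1] <- 0                      # DC-blocked bandpass
  stats::fft(X * H, inverse = TRUE) / length(X)
}

#' Modulation stage of the auditory model
#'
#' In `lp` mode each channel is smoothed by a first-order 8 Hz lowpass
#' (the classic decision-stage preprocessing), giving a 2-D
#' representation.  In `fb` mode each channel is analysed by a modulation
#' filterbank (a 2.5 Hz lowpass plus log-spaced bandpass bands up to about
#' 129 Hz); the band output is the real part of the complex band signal
#' for centres at or below 10 Hz and its magnitude (envelope) above,
#' giving a 3-D representation.  The output is decimated to a frame rate
#' sufficient for the retained modulation content.
#'
#' @param adapted Matrix (time x channels) from [adaptation_stage()].
#' @param sample_rate_hz Rate of `adapted`.
#' @param mode `"lp"` or `"fb"`.
#' @param lp_cutoff_hz Cutoff of the lp-mode lowpass.
#' @param decimate Integer decimation factor applied after filtering.
#' @return An `internal_representation` object: list with `values`
#'   (matrix or 3-D array time x channel\[ x modulation band\]),
#'   `frame_rate_hz`, `mode`.
#' @export
modulation_stage <- function(adapted, sample_rate_hz, mode = c("lp", "fb"),
                             lp_cutoff_hz = 8,
                             decimate = if (mode[1] == "lp") 128L else 32L) {
  mode <- match.arg(mode)
  n <- nrow(adapted); nch <- ncol(adapted)
  decimate <- max(1L, as.integer(decimate))
  keep <- seq(1L, n, by = decimate)
  freqs <- (0:(n - 1L)) * sample_rate_hz / n
  if (mode == "lp") {
    vals <- matrix(0, length(keep), nch)
    f <- ifelse(freqs > sample_rate_hz / 2, freqs - sample_rate_hz, freqs)
    H <- 1 / (1 + 1i * f / lp_cutoff_hz)
    for (c in seq_len(nch)) {
      y <- Re(stats::fft(stats::fft(adapted[, c]) * H, inverse = TRUE)) / n
      vals[, c] <- y[keep]
    }
  } else {
    bands <- modulation_bands()
    vals <- array(0, c(length(keep), nch, nrow(bands)))
    for (c in seq_len(nch)) {
      X <- stats::fft(adapted[, c])
      for (b in seq_len(nrow(bands))) {
        z <- mod_filter_apply(X, freqs, sample_rate_hz,
                              bands$center_hz[b], bands$bandwidth_hz[b])
        y <- if (bands$center_hz[b] <= 10) Re(z) else Mod(z)
        vals[, c, b] <- y[keep]
      }
    }
  }
  structure(list(values = vals,
                 frame_rate_hz = sample_rate_hz / decimate,
                 mode = mode),
            class = "internal_representation")
}

#' @export
print.internal_representation <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("internal representation (%s): %s @ %.1f Hz frame rate\n",
              x$mode, paste(d, collapse = " x "), x$frame_rate_hz))
  invisible(x)
}

#' Compute the internal representation of a signal
#'
#' Full auditory front-end: gammatone filterbank and envelope extraction,
#' optional hearing-impairment stage (attenuation + expansion from the
#' IHC/OHC decomposition of an audiogram), adaptation loops, and the
#' modulation stage.  Deterministic for fixed input.  An audiogram of all
#' zeros reproduces the normal-hearing path exactly.
#'
#' @param signal An [audio_signal()] at the filterbank rate.
#' @param fb A [design_filterbank()] spec.
#' @param ag An [audiogram()] or `NULL` for normal hearing.
#' @param mode Modulation mode, `"lp"` or `"fb"`.
#' @param hi_params List of hearing-impairment parameters
#'   (`ohc_fraction`, `ohcl_cap`, `convergence_db`, `gamma`).
#' @param env_decimate Decimation factor applied between the adaptation
#'   and modulation stages (the envelope path runs at the full signal rate
#'   through the instantaneous stages; modulation content above ~130 Hz is
#'   not needed downstream).
#' @return An `internal_representation`.
#' @export
compute_internal_representation <- function(signal, fb, ag = NULL,
                                            mode = c("lp", "fb"),
                                            hi_params = list(),
                                            env_decimate = 32L) {
  mode <- match.arg(mode)
  env <- peripheral_and_envelope(signal, fb)
  if (!is.null(ag)) {
    hp <- utils::modifyList(list(ohc_fraction = 0.8, ohcl_cap = 55,
                                 convergence_db = 100, gamma = 2), hi_params)
    losses <- decompose_hearing_loss(ag, fb, hp$ohc_fraction, hp$ohcl_cap)
    env <- hi_stage(env, losses, spl_reference_db = signal$spl_reference_db,
                    convergence_db = hp$convergence_db, gamma = hp$gamma)
  }
  adapted <- adaptation_stage(env, signal$sample_rate_hz)
  # decimate (boxcar mean) before modulation filtering; block mean keeps
  # modulation content far below the new Nyquist intact
  d <- max(1L, as.integer(env_decimate))
  if (d > 1L) {
    n2 <- (nrow(adapted) %/% d) * d
    adapted <- apply(adapted[1:n2, , drop = FALSE], 2, function(v)
      colMeans(matrix(v, nrow = d)))
  }
  fs2 <- signal$sample_rate_hz / d
  ir <- modulation_stage(adapted, fs2, mode,
                         decimate = if (mode == "lp") 4L else 1L)
  ir$filterbank <- fb
  ir
}
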