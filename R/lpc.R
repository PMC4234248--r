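# ---------------------------------------------------------------------------
# Classic LPC-domain quality distances: Itakura-Saito distance (ISD),
# log-area ratio (LAR), log-likelihood ratio (LLR) and the weighted
# spectral slope distance (WSSD).  Conventional narrowband analysis:
# signals are resampled to 8 kHz, framed at 32 ms / 16 ms hop with a
# Hamming window, LPC order 10.
# ---------------------------------------------------------------------------

#' Levinson-Durbin LPC analysis of one frame
#'
#' Solves the autocorrelation normal equations.  Returns the monic
#' prediction-error filter `a = (1, a_1, ..., a_P)`, the residual energy
#' `gain`, the reflection coefficients, and the biased autocorrelation at
#' lags 0..P.  Zero-energy frames are flagged silent.
#'
#' @param x Numeric frame (length > `order`).
#' @param order LPC order P.
#' @return List of class `lpc_frame` with fields `a`, `gain`, `reflection`,
#'   `autocorrelation`, `silent`.
#' @export
lpc_analyze <- function(x, order = 10) {
  n <- length(x)
  if (n <= order) stop("lpc_analyze: frame shorter than the LPC order")
  r <- sapply(0:order, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n)
  if (r[1] <= 0) {
    return(structure(list(a = c(1, numeric(order)), gain = 0,
                          reflection = numeric(order),
                          autocorrelation = r, silent = TRUE),
                     class = "lpc_frame"))
  }
  a <- 1
  e <- r[1]
  k_all <- numeric(order)
  for (i in 1:order) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc + sum(a[2:i] * r[i:2])
    k <- -acc / e
    k_all[i] <- k
    a <- c(a, 0)
    a <- a + k * rev(a)
    e <- e * (1 - k^2)
    if (e <= 0) { e <- .Machine$double.eps; break }
  }
  structure(list(a = a, gain = e, reflection = k_all,
                 autocorrelation = r, silent = FALSE),
            class = "lpc_frame")
}

#' Build an `lpc_frame` directly from known AR coefficients
#'
#' For oracle computations: given a stable AR model
#' `x[n] = -sum(a_k x[n-k]) + e[n]` with innovation variance `gain`,
#' derives the exact model autocorrelation (by solving the Yule-Walker
#' system in reverse) and the reflection coefficients.
#'
#' @param a Monic coefficient vector `(1, a_1, ..., a_P)`.
#' @param gain Innovation variance (> 0).
#' @param n_lags Autocorrelation lags to tabulate (>= P).
#' @return An `lpc_frame`.
#' @export
lpc_frame_from_ar <- function(a, gain = 1, n_lags = length(a) - 1L) {
  p <- length(a) - 1L
  # autocovariance of the AR process via spectral integration on a fine grid
  ng <- 8192L
  w <- 2 * pi * (0:(ng - 1L)) / ng
  A <- sapply(seq_len(ng), function(j) sum(a * exp(-1i * w[j] * (0:p))))
  S <- gain / Mod(A)^2
  r <- sapply(0:n_lags, function(k) Re(mean(S * exp(1i * w * k))))
  # reflection coefficients via reverse Levinson
  refl <- rev_levinson(a)
  structure(list(a = a, gain = gain, reflection = refl,
                 autocorrelation = r, silent = FALSE),
            class = "lpc_frame")
}

rev_levinson <- function(a) {
  p <- length(a) - 1L
  refl <- numeric(p)
  cur <- a
  for (i in p:1) {
    k <- cur[i + 1L]
    refl[i] <- k
    if (i > 1L) {
      denom <- 1 - k^2
      if (denom <= 0) stop("rev_levinson: unstable filter")
      cur <- (cur[1:i] - k * rev(cur[1:i])) / denom
    }
  }
  refl
}

toeplitz_quad <- function(a, r) {
  # a' R a for Toeplitz R built from autocorrelation r[0..P]
  p <- length(a) - 1L
  R <- stats::toeplitz(r[1:(p + 1L)])
  as.numeric(t(a) %*% R %*% a)
}

#' Itakura-Saito distance between two LPC frames
#'
#' Classic IS spectral distortion between the all-pole model spectra
#' `P(w) = gain / |A(w)|^2`:
#' `d_IS = mean(P_ref/P_test - log(P_ref/P_test) - 1) >= 0`, evaluated in
#' closed form via the reference autocorrelation:
#' `d_IS = (a_t' R_r a_t)/g_t - log(g_r/g_t) - 1`
#' with `g_r = a_r' R_r a_r`.  Asymmetric in its arguments.
#'
#' @param ref,test `lpc_frame`s of equal order.
#' @return Nonnegative scalar (0 iff the model spectra are equal).
#' @export
isd <- function(ref, test) {
  if (length(ref$a) != length(test$a)) stop("isd: orders differ")
  if (ref$silent || test$silent) return(NA_real_)
  num <- toeplitz_quad(test$a, ref$autocorrelation)
  g_r <- toeplitz_quad(ref$a, ref$autocorrelation)
  num / test$gain - log(g_r / test$gain) - 1
}

#' Log-likelihood ratio between two LPC frames
#'
#' `llr = log( (a_t' R_r a_t) / (a_r' R_r a_r) )` with `R_r` the Toeplitz
#' autocorrelation matrix of the reference frame; >= 0, 0 iff the
#' coefficient vectors match.
#'
#' @param ref,test `lpc_frame`s of equal order.
#' @return Nonnegative scalar.
#' @export
llr <- function(ref, test) {
  if (length(ref$a) != length(test$a)) stop("llr: orders differ")
  if (ref$silent || test$silent) return(NA_real_)
  log(toeplitz_quad(test$a, ref$autocorrelation) /
      toeplitz_quad(ref$a, ref$autocorrelation))
}

#' Log-area-ratio distance between two LPC frames
#'
#' RMS difference of the log-area ratios
#' `LAR_j = log((1 + k_j)/(1 - k_j))` derived from the reflection
#' coefficients; symmetric, 0 iff the reflection coefficients match.
#'
#' @param ref,test `lpc_frame`s of equal order.
#' @return Nonnegative scalar.
#' @export
lar <- function(ref, test) {
  if (length(ref$reflection) != length(test$reflection))
    stop("lar: orders differ")
  if (ref$silent || test$silent) return(NA_real_)
  if (any(abs(ref$reflection) >= 1) || any(abs(test$reflection) >= 1))
    stop("lar: invalid frame (|reflection coefficient| >= 1)")
  g <- function(k) log((1 + k) / (1 - k))
  sqrt(mean((g(ref$reflection) - g(test$reflection))^2))
}

# --- critical-band front end for the WSSD ---------------------------------

bark_from_hz <- function(f) 13 * atan(0.00076 * f) + 3.5 * atan((f / 7500)^2)

# Triangular critical-band filters, centres equally spaced on the Bark
# scale; returns band energies of a power spectrum.
critical_band_energies <- function(px, freqs, n_bands, f_max) {
  z <- bark_from_hz(freqs)
  z_max <- bark_from_hz(f_max)
  centers <- seq(z_max / (n_bands + 1), z_max * n_bands / (n_bands + 1),
                 length.out = n_bands)
  half <- diff(centers[1:2])
  sapply(centers, function(zc) {
    w <- pmax(0, 1 - abs(z - zc) / half)
    sum(w * px)
  })
}

#' Weighted spectral slope distance between two signals
#'
#' Frame-based Klatt measure: per frame, critical-band log-magnitude
#' spectra are computed for reference and test, the slopes (first
#' differences across bands, dB) are compared, and squared slope
#' differences are averaged with weights that emphasise spectral peaks
#' (`w = (K_max/(K_max + dB_max - E)) * (K_loc/(K_loc + dB_locmax - E))`,
#' averaged between reference and test).  Invariant to a common gain on
#' both signals; 0 for identical signals.
#'
#' @param ref,test [audio_signal()]s at equal rates, frame-aligned.
#' @param frame_len,hop Frame length and hop in samples.
#' @param n_bands Number of critical bands.
#' @param k_max,k_locmax Klatt weighting constants.
#' @param silence_db Frames below this level (dBFS) in either signal are
#'   excluded.
#' @param trim Upper trimming quantile for the frame average.
#' @return Nonnegative scalar.
#' @export
wssd <- function(ref, test, frame_len = 256, hop = 128, n_bands = 25,
                 k_max = 20, k_locmax = 1, silence_db = -60, trim = 0.95) {
  if (ref$sample_rate_hz != test$sample_rate_hz)
    stop("wssd: sample rates differ")
  fs <- ref$sample_rate_hz
  n <- min(length(ref$samples), length(test$samples))
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_len - 1)) / (frame_len - 1))
  nfft <- 2 * frame_len
  freqs <- (0:(nfft / 2)) * fs / nfft
  starts <- seq(1, n - frame_len + 1, by = hop)
  dists <- numeric(0)
  for (s in starts) {
    xr <- ref$samples[s:(s + frame_len - 1)]
    xt <- test$samples[s:(s + frame_len - 1)]
    if (10 * log10(mean(xr^2) + 1e-300) < silence_db ||
        10 * log10(mean(xt^2) + 1e-300) < silence_db) next
    d <- wssd_frame_bands(xr * win, xt * win, nfft, freqs, fs, n_bands,
                          k_max, k_locmax)
    dists <- c(dists, d)
  }
  if (length(dists) == 0L) return(NA_real_)
  trimmed_mean(dists, trim)
}

wssd_frame_bands <- function(xr, xt, nfft, freqs, fs, n_bands,
                             k_max, k_locmax) {
  pr <- Mod(stats::fft(c(xr, numeric(nfft - length(xr)))))[1:(nfft / 2 + 1)]^2
  pt <- Mod(stats::fft(c(xt, numeric(nfft - length(xt)))))[1:(nfft / 2 + 1)]^2
  er <- 10 * log10(critical_band_energies(pr, freqs, n_bands, fs / 2) + 1e-300)
  et <- 10 * log10(critical_band_energies(pt, freqs, n_bands, fs / 2) + 1e-300)
  wssd_from_band_energies(er, et, k_max, k_locmax)
}

# Klatt slope comparison on precomputed band energies (dB); exported for
# oracle-style checks on synthetic band patterns.
#' @rdname wssd
#' @param er,et Band energies in dB for reference and test.
#' @export
wssd_from_band_energies <- function(er, et, k_max = 20, k_locmax = 1) {
  sr <- diff(er); st <- diff(et)
  wr <- klatt_weights(er, k_max, k_locmax)
  wt <- klatt_weights(et, k_max, k_locmax)
  w <- (wr + wt) / 2
  sum(w * (sr - st)^2) / sum(w)
}

klatt_weights <- function(e, k_max, k_locmax) {
  n <- length(e)
  gmax <- max(e)
  # nearest local maximum in the direction of the slope
  locmax <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    if (e[k + 1] > e[k]) {           # rising: walk forward to the peak
      j <- k + 1
      while (j < n && e[j + 1] > e[j]) j <- j + 1
    } else {                         # falling: walk back to the peak
      j <- k
      while (j > 1 && e[j - 1] > e[j]) j <- j - 1
    }
    locmax[k] <- e[j]
  }
  eh <- e[1:(n - 1)]
  (k_max / (k_max + gmax - eh)) * (k_locmax / (k_locmax + locmax - eh))
}

trimmed_mean <- function(x, q) {
  x <- x[!is.na(x)]
  mean(x[x <= stats::quantile(x, q)])
}

#' Frame-averaged LPC distance between two signals
#'
#' Shared driver for the ISD, LAR and LLR measures: the signals are
#' resampled to `analysis_rate_hz`, framed (Hamming window), silent frames
#' (below `silence_db` dBFS in either signal) are excluded jointly, the
#' per-frame distance is computed, and frames are aggregated by a trimmed
#' mean over the lowest `trim` quantile.
#'
#' @param test,ref [audio_signal()]s.
#' @param measure One of `"isd"`, `"lar"`, `"llr"`, `"wssd"`.
#' @param analysis_rate_hz Analysis rate (default 8 kHz; 16 kHz extends
#'   the band to 8 kHz).
#' @param order LPC order.
#' @param frame_s,hop_s Frame length and hop in seconds.
#' @param silence_db Joint silence threshold (dBFS).
#' @param trim Trimming quantile for the frame average.
#' @return Nonnegative scalar distance.
#' @export
lpc_distance <- function(test, ref, measure = c("isd", "lar", "llr", "wssd"),
                         analysis_rate_hz = 8000, order = 10,
                         frame_s = 0.032, hop_s = 0.016,
                         silence_db = -60, trim = 0.95) {
  measure <- match.arg(measure)
  test <- resample_signal(test, analysis_rate_hz)
  ref <- resample_signal(ref, analysis_rate_hz)
  al <- align_and_scale(test, ref)
  test <- al$test; ref <- al$ref
  frame_len <- round(frame_s * analysis_rate_hz)
  hop <- round(hop_s * analysis_rate_hz)
  if (measure == "wssd")
    return(wssd(ref, test, frame_len = frame_len, hop = hop,
                silence_db = silence_db, trim = trim))
  win <- 0.54 - 0.46 * cos(2 * pi * (0:(frame_len - 1)) / (frame_len - 1))
  n <- min(length(test$samples), length(ref$samples))
  starts <- seq(1, n - frame_len + 1, by = hop)
  fun <- switch(measure, isd = isd, lar = lar, llr = llr)
  dists <- numeric(0)
  for (s in starts) {
    xr <- ref$samples[s:(s + frame_len - 1)]
    xt <- test$samples[s:(s + frame_len - 1)]
    if (10 * log10(mean(xr^2) + 1e-300) < silence_db ||
        10 * log10(mean(xt^2) + 1e-300) < silence_db) next
    fr <- lpc_analyze(xr * win, order)
    ft <- lpc_analyze(xt * win, order)
    if (fr$silent || ft$silent) next
    d <- tryCatch(fun(fr, ft), error = function(e) NA_real_)
    if (!is.na(d)) dists <- c(dists, d)
  }
  if (length(dists) == 0L) return(NA_real_)
  trimmed_mean(dists, trim)
}
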