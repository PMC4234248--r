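#' Audiogram container
#'
#' @param freqs_hz Ascending audiometric frequencies in Hz (>= 2).
#' @param thresholds_db_hl Matching hearing thresholds in dB HL, within
#'   \[-20, 120\].
#' @return An object of class `audiogram`.
#' @export
audiogram <- function(freqs_hz, thresholds_db_hl) {
  if (length(freqs_hz) < 2L || length(freqs_hz) != length(thresholds_db_hl))
    stop("audiogram: need >= 2 matching (frequency, threshold) pairs")
  if (is.unsorted(freqs_hz, strictly = TRUE))
    stop("audiogram: frequencies must be strictly ascending")
  if (any(thresholds_db_hl < -20 | thresholds_db_hl > 120))
    stop("audiogram: thresholds must lie within [-20, 120] dB HL")
  structure(list(freqs_hz = as.numeric(freqs_hz),
                 thresholds_db_hl = as.numeric(thresholds_db_hl)),
            class = "audiogram")
}

#' Read an audiogram from a two-column delimited text file (Hz, dB HL)
#' @param path File path; columns separated by whitespace, tab or comma.
#' @return An [audiogram()].
#' @export
read_audiogram <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_audiogram: no such file: %s", path))
  tab <- utils::read.table(path, header = FALSE, sep = "",
                           comment.char = "#",
                           col.names = c("freq", "thr"))
  audiogram(tab$freq, tab$thr)
}

#' A representative steeply sloping high-frequency audiogram (synthetic)
#'
#' A moderately severe-to-profound sloping sensorineural loss of the kind
#' that motivates frequency-lowering fittings.  This is a synthetic
#' representative configuration, not measured data.
#'
#' @return An [audiogram()].
#' @export
example_audiogram <- function() {
  audiogram(c(250, 500, 1000, 2000, 3000, 4000, 6000, 8000),
            c(20, 30, 40, 55, 65, 70, 75, 80))
}

#' Decompose total hearing loss into inner/outer hair cell contributions
#'
#' Audiometric thresholds are interpolated to the filterbank centre
#' frequencies (linear in log-frequency vs. dB, flat extrapolation beyond
#' the outermost audiometric points).  Per channel the total loss HL is
#' split as `OHCL = min(ohc_fraction * HL, ohcl_cap)` and
#' `IHCL = HL - OHCL`, following the convention that outer hair cell loss
#' accounts for the bulk of a sensorineural loss up to a cap.
#'
#' @param ag An [audiogram()].
#' @param fb A [design_filterbank()] spec.
#' @param ohc_fraction Fraction of the total loss attributed to OHCs.
#' @param ohcl_cap Maximum OHC loss in dB.
#' @return A data frame with columns `center_freq_hz`, `total_hl_db`,
#'   `ihcl_db`, `ohcl_db` (one row per channel).
#' @export
decompose_hearing_loss <- function(ag, fb, ohc_fraction = 0.8,
                                   ohcl_cap = 55) {
  if (!inherits(ag, "audiogram")) stop("decompose_hearing_loss: need an audiogram")
  cfs <- fb$center_freqs_hz
  hl <- stats::approx(log(ag$freqs_hz), ag$thresholds_db_hl, xout = log(cfs),
                      rule = 2)$y
  hl <- pmax(hl, 0)
  ohcl <- pmin(ohc_fraction * hl, ohcl_cap)
  ihcl <- hl - ohcl
  data.frame(center_freq_hz = cfs, total_hl_db = hl,
             ihcl_db = ihcl, ohcl_db = ohcl)
}

#' Instantaneous attenuation and expansion stage (hearing impairment)
#'
#' Operates sample-by-sample on each channel envelope, after envelope
#' extraction and before the adaptation loops.  The amplitude is first
#' attenuated by IHCL dB.  It is then passed through an expansive
#' input/output function driven by OHCL: writing the instantaneous level
#' as `L = spl_reference_db + 20 log10(a)`, the output level is
#' \deqn{L_{out} = L - OHCL ((L_{conv} - L)/L_{conv})^\gamma, \quad L < L_{conv}}
#' and `L_out = L` above the convergence level `L_conv`.  The dB-domain
#' slope is therefore `>= 1` everywhere, largest at low levels, and decays
#' smoothly to 1 at `L_conv` (for `gamma > 1`); a sample at audiometric
#' zero (`L = 0`) is attenuated by exactly OHCL, so together with the IHCL
#' attenuation the detection threshold is raised by the full hearing loss.
#' With zero loss the stage is the exact identity.
#'
#' @param envelopes Nonnegative matrix (time x channels) from
#'   [peripheral_and_envelope()].
#' @param losses Data frame from [decompose_hearing_loss()], one row per
#'   channel.
#' @param spl_reference_db Calibration convention (full-scale RMS level).
#' @param convergence_db Level at which the I/O function joins the
#'   identity (dB).
#' @param gamma Curvature of the expansion (> 1).
#' @return Matrix of the same shape.
#' @export
hi_stage <- function(envelopes, losses, spl_reference_db = 100,
                     convergence_db = 100, gamma = 2) {
  if (nrow(losses) != ncol(envelopes))
    stop("hi_stage: one ChannelLoss row per channel required")
  out <- envelopes
  for (c in seq_len(ncol(envelopes))) {
    ihcl <- losses$ihcl_db[c]
    ohcl <- losses$ohcl_db[c]
    if (ihcl == 0 && ohcl == 0) next
    a <- envelopes[, c] * 10^(-ihcl / 20)
    if (ohcl > 0) {
      pos <- a > 0
      L <- spl_reference_db + 20 * log10(a[pos])
      att <- numeric(length(L))
      below <- L < convergence_db
      att[below] <- ohcl *
        ((convergence_db - L[below]) / convergence_db)^gamma
      a[pos] <- a[pos] * 10^(-att / 20)
    }
    out[, c] <- a
  }
  out
}
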