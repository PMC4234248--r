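#' Quality measure options
#'
#' Options controlling the PSM / qc computation: modulation mode,
#' frequency-band importance weighting (+/-W), asymmetric assimilation of
#' internal-representation differences (+/-B, "Beerends weighting"), and
#' the hearing model (normal hearing or an audiogram).
#'
#' @param modulation_mode `"lp"` or `"fb"`.
#' @param band_weighting Logical; apply the band-importance weighting.
#' @param assimilation Logical; apply asymmetric assimilation.
#' @param hearing `NULL` (normal hearing) or an [audiogram()].
#' @return A list of class `quality_options`.
#' @export
quality_options <- function(modulation_mode = c("lp", "fb"),
                            band_weighting = FALSE,
                            assimilation = FALSE,
                            hearing = NULL) {
  modulation_mode <- match.arg(modulation_mode)
  if (!is.null(hearing) && !inherits(hearing, "audiogram"))
    stop("quality_options: 'hearing' must be NULL or an audiogram")
  structure(list(modulation_mode = modulation_mode,
                 band_weighting = isTRUE(band_weighting),
                 assimilation = isTRUE(assimilation),
                 hearing = hearing),
            class = "quality_options")
}

#' Asymmetric assimilation of internal representations
#'
#' Wherever the test representation falls below the reference, the
#' difference is halved (`test' = test + 0.5 (ref - test)`); positive
#' deviations are kept unchanged.  This reflects the hypothesis that
#' missing components are perceptually less disturbing than added ones.
#'
#' @param ir_test,ir_ref `internal_representation`s of identical shape.
#' @return The assimilated test representation.
#' @export
assimilate <- function(ir_test, ir_ref) {
  if (!identical(dim(ir_test$values), dim(ir_ref$values)))
    stop("assimilate: representations have different shapes")
  t <- ir_test$values; r <- ir_ref$values
  low <- t < r
  t[low] <- t[low] + 0.5 * (r[low] - t[low])
  ir_test$values <- t
  ir_test
}

#' Band-importance weighting of an internal representation
#'
#' Multiplies each peripheral channel by a nonnegative weight.
#'
#' @param ir An `internal_representation`.
#' @param weights One weight per channel, >= 0.
#' @return The weighted representation.
#' @export
band_weighting <- function(ir, weights) {
  nch <- dim(ir$values)[2]
  if (length(weights) != nch)
    stop("band_weighting: need one weight per channel")
  if (any(weights < 0)) stop("band_weighting: weights must be >= 0")
  if (length(dim(ir$values)) == 2L) {
    ir$values <- sweep(ir$values, 2, weights, `*`)
  } else {
    ir$values <- sweep(ir$values, 2, weights, `*`)
  }
  ir
}

#' Default band-importance weights
#'
#' Monotone weighting that emphasises the higher-frequency channels of a
#' telephone-band representation (unity up to 1 kHz, rising linearly in
#' log-frequency above it).  Used for the `+W` option of the qc measure.
#'
#' @param center_freqs_hz Channel centre frequencies.
#' @return Numeric weight vector.
#' @export
default_band_weights <- function(center_freqs_hz) {
  1 + pmax(0, log2(center_freqs_hz / 1000))
}

#' Perceptual similarity measure between internal representations
#'
#' The overall Pearson correlation of the two complete representations,
#' flattened jointly across time, channel and (if present) modulation
#' band.  Lies in \[-1, 1\]; 1 for identical (or positively affine-related)
#' representations.
#'
#' @param ir_test,ir_ref `internal_representation`s of identical shape.
#' @return Scalar correlation.
#' @export
psm <- function(ir_test, ir_ref) {
  if (!identical(dim(ir_test$values), dim(ir_ref$values)))
    stop("psm: representations have different shapes")
  t <- as.vector(ir_test$values); r <- as.vector(ir_ref$values)
  if (length(r) < 2L) stop("psm: need at least 2 elements")
  if (stats::sd(r) == 0) {
    if (isTRUE(all.equal(t, r, tolerance = 1e-12))) return(1)
    stop("psm: constant reference representation")
  }
  if (stats::sd(t) == 0) {
    stop("psm: constant test representation")
  }
  stats::cor(t, r)
}

#' Hansen-model quality measure qc
#'
#' Overall correlation of (optionally band-weighted, optionally
#' assimilated) internal representations from the telephone-band model.
#'
#' @param ir_test,ir_ref `internal_representation`s computed with the
#'   qc filterbank (upper edge 4 kHz).
#' @param options A [quality_options()].
#' @param weights Optional per-channel weights; defaults to
#'   [default_band_weights()] of the filterbank centres when
#'   `options$band_weighting` is on.
#' @return Scalar correlation.
#' @export
qc <- function(ir_test, ir_ref, options = quality_options(),
               weights = NULL) {
  if (options$band_weighting) {
    if (is.null(weights)) {
      cfs <- ir_ref$filterbank$center_freqs_hz
      if (is.null(cfs)) stop("qc: no filterbank metadata for weighting")
      weights <- default_band_weights(cfs)
    }
    ir_test <- band_weighting(ir_test, weights)
    ir_ref <- band_weighting(ir_ref, weights)
  }
  if (options$assimilation) ir_test <- assimilate(ir_test, ir_ref)
  psm(ir_test, ir_ref)
}

#' Peripheral filterbank edges for each measure family
#'
#' PSM analyses the wideband range (235 Hz - 15.3 kHz); qc uses the
#' telephone-band range (235 Hz - 4 kHz).
#'
#' @param measure `"psm"` or `"qc"`.
#' @param sample_rate_hz Working rate (the upper edge is clipped below
#'   Nyquist).
#' @return A [design_filterbank()] spec.
#' @export
measure_filterbank <- function(measure = c("psm", "qc"),
                               sample_rate_hz = 22050) {
  measure <- match.arg(measure)
  f_hi <- if (measure == "psm") 15300 else 4000
  f_hi <- min(f_hi, sample_rate_hz / 2 * 0.999)
  design_filterbank(sample_rate_hz, 235, f_hi)
}

#' Predict the quality of a test signal against a reference
#'
#' End-to-end score: the signals are resampled to the working rate,
#' time-aligned and level-matched, scaled to the presentation level, both
#' passed through the identically configured auditory front-end (for the
#' HI variants the same audiogram-configured model processes both paths),
#' and the selected measure with its options is computed on the internal
#' representations.  No regression mapping is applied to the score.
#'
#' @param test,ref [audio_signal()]s.
#' @param measure `"psm"` or `"qc"`.
#' @param options A [quality_options()].
#' @param level_db Presentation level (dB SPL) both signals are scaled to.
#' @param working_rate_hz Internal model rate.
#' @param hi_params Passed to [compute_internal_representation()].
#' @return A list of class `quality_score` with `value`, `measure_name`,
#'   `options`.
#' @export
predict_quality <- function(test, ref, measure = c("psm", "qc"),
                            options = quality_options(),
                            level_db = 65, working_rate_hz = 22050,
                            hi_params = list()) {
  measure <- match.arg(measure)
  if (length(test$samples) == 0L || length(ref$samples) == 0L)
    stop("predict_quality: empty signal")
  test <- resample_signal(test, working_rate_hz)
  ref <- resample_signal(ref, working_rate_hz)
  al <- align_and_scale(test, ref)
  ref_l <- set_level(al$ref, level_db)
  # preserve the test/ref level relation established by align_and_scale
  test_l <- al$test
  test_l$samples <- test_l$samples * (10^((level_db - signal_level_db(al$ref)) / 20))
  fb <- measure_filterbank(measure, working_rate_hz)
  ir_t <- compute_internal_representation(test_l, fb, ag = options$hearing,
                                          mode = options$modulation_mode,
                                          hi_params = hi_params)
  ir_r <- compute_internal_representation(ref_l, fb, ag = options$hearing,
                                          mode = options$modulation_mode,
                                          hi_params = hi_params)
  value <- if (measure == "psm") {
    ir_t2 <- ir_t
    if (options$band_weighting) {
      w <- default_band_weights(fb$center_freqs_hz)
      ir_t2 <- band_weighting(ir_t2, w)
      ir_r <- band_weighting(ir_r, w)
    }
    if (options$assimilation) ir_t2 <- assimilate(ir_t2, ir_r)
    psm(ir_t2, ir_r)
  } else {
    qc(ir_t, ir_r, options)
  }
  structure(list(value = value,
                 measure_name = measure_label(measure, options),
                 options = options),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf("%s = %.4f\n", x$measure_name, x$value))
  invisible(x)
}

measure_label <- function(measure, options) {
  base <- if (measure == "psm")
    paste0("PSM_", options$modulation_mode)
  else "qc"
  w <- if (measure == "qc" || options$band_weighting)
    paste0(if (options$band_weighting) "+" else "-", "W") else ""
  b <- paste0(if (options$assimilation) "+" else "-", "B")
  hi <- if (!is.null(options$hearing)) " (HI)" else ""
  paste0(base, w, b, hi)
}
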