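test_that("filterbank centres follow the ERB scale between the edges", {
  fb <- design_filterbank(22050, 235, 4000)
  expect_true(all(diff(fb$center_freqs_hz) > 0))
  expect_lte(max(fb$center_freqs_hz), 4000 + 1e-9)
  expect_gte(min(fb$center_freqs_hz), 235 - 1e-9)
  # channel count matches the analytic ERB-number difference within 1
  expect_lt(abs(length(fb$center_freqs_hz) -
                (erb_number(4000) - erb_number(235))), 1 + 1e-9)
  # wideband variant reaches but does not exceed 15.3 kHz
  fbw <- design_filterbank(44100, 235, 15300)
  expect_lte(max(fbw$center_freqs_hz), 15300 + 1e-9)
  # degenerate single-filter bank
  fb1 <- design_filterbank(22050, 1000, 1000)
  expect_length(fb1$center_freqs_hz, 1)
  expect_error(design_filterbank(22050, 235, 12000), "Nyquist")
})

test_that("peripheral filtering and envelope extraction behave physically", {
  fs <- 22050
  fb <- design_filterbank(fs, 235, 8000)
  # silence -> all-zero envelopes
  env0 <- peripheral_and_envelope(audio_signal(numeric(fs %/% 2) + 0, fs), fb)
  expect_equal(max(abs(env0)), 0)
  # on-centre tone dominates channels >= 2 ERB away
  cfs <- fb$center_freqs_hz
  ch <- which.min(abs(cfs - 1000))
  env <- peripheral_and_envelope(tone_signal(cfs[ch], duration_s = 0.4), fb)
  m <- colMeans(env[4000:nrow(env), ])
  far <- abs(erb_number(cfs) - erb_number(cfs[ch])) >= 2
  expect_gt(m[ch] / max(m[far]), 10)
  expect_true(all(env >= 0))
})

test_that("envelope extraction preserves slow amplitude modulation depth", {
  fs <- 22050
  fb <- design_filterbank(fs, 900, 1100)
  t <- (0:(fs - 1)) / fs
  x <- audio_signal((1 + 0.5 * sin(2 * pi * 4 * t)) * 0.2 * sin(2 * pi * 1000 * t), fs)
  env <- peripheral_and_envelope(x, fb)
  ch <- which.min(abs(fb$center_freqs_hz - 1000))
  e <- env[4410:fs, ch]
  # demodulate: modulation depth = AC amplitude at 4 Hz / DC
  n <- length(e)
  sp <- Mod(stats::fft(e - mean(e)))
  b4 <- round(4 * n / fs) + 1
  depth <- 2 * max(sp[(b4 - 1):(b4 + 1)]) / n / mean(e)
  expect_lt(abs(depth - 0.5), 0.05)
})

test_that("hearing-loss decomposition interpolates and splits with a cap", {
  fb <- design_filterbank(22050, 235, 8000)
  # zero audiogram -> all zeros
  z <- decompose_hearing_loss(audiogram(c(250, 8000), c(0, 0)), fb)
  expect_true(all(z$ihcl_db == 0) && all(z$ohcl_db == 0))
  # flat 50 dB: OHCL = 40, IHCL = 10 under the 0.8/55 split
  d50 <- decompose_hearing_loss(audiogram(c(250, 8000), c(50, 50)), fb)
  expect_equal(d50$ohcl_db, rep(40, nrow(d50)))
  expect_equal(d50$ihcl_db, rep(10, nrow(d50)))
  # flat 80 dB: cap active -> OHCL = 55, IHCL = 25
  d80 <- decompose_hearing_loss(audiogram(c(250, 8000), c(80, 80)), fb)
  expect_equal(d80$ohcl_db, rep(55, nrow(d80)))
  expect_equal(d80$ihcl_db, rep(25, nrow(d80)))
  # components always sum to the interpolated total
  ag <- example_audiogram()
  d <- decompose_hearing_loss(ag, fb)
  expect_equal(d$ihcl_db + d$ohcl_db, d$total_hl_db)
  expect_true(all(d$ihcl_db >= 0 & d$ohcl_db >= 0))
})

test_that("hi_stage implements attenuation plus level-dependent expansion", {
  env <- matrix(10^(seq(-4, 0, length.out = 50)), ncol = 1)
  zero <- data.frame(center_freq_hz = 1000, total_hl_db = 0,
                     ihcl_db = 0, ohcl_db = 0)
  expect_identical(hi_stage(env, zero), env)
  # pure IHCL attenuation: exactly 10^(-IHCL/20)
  ihc <- data.frame(center_freq_hz = 1000, total_hl_db = 20,
                    ihcl_db = 20, ohcl_db = 0)
  expect_equal(hi_stage(env, ihc), env * 10^(-1))
  # OHCL = 40: dB-domain slope > 1 at low levels, decreasing toward 1
  ohc <- data.frame(center_freq_hz = 1000, total_hl_db = 40,
                    ihcl_db = 0, ohcl_db = 40)
  lev_in <- seq(20, 95, by = 5)
  out <- hi_stage(matrix(10^((lev_in - 100) / 20), ncol = 1), ohc)
  lev_out <- 100 + 20 * log10(out[, 1])
  slopes <- diff(lev_out) / diff(lev_in)
  expect_true(all(slopes >= 1 - 1e-9))
  expect_gt(slopes[1], 1.05)
  expect_true(all(diff(slopes) < 1e-9))     # decreasing toward 1
  expect_lt(slopes[length(slopes)], slopes[1])
  # a sample at audiometric zero is attenuated by the full loss
  a0 <- 10^((0 - 100) / 20)
  out0 <- hi_stage(matrix(a0, 1, 1), ohc)
  expect_equal(20 * log10(out0[1, 1] / a0), -40, tolerance = 1e-9)
})

test_that("hi_stage output is monotone in IHCL and OHCL", {
  lev <- matrix(10^(seq(-4, -0.5, length.out = 30)), ncol = 1)
  prev <- NULL
  for (ihcl in c(0, 10, 20, 40)) {
    l <- data.frame(center_freq_hz = 1000, total_hl_db = ihcl,
                    ihcl_db = ihcl, ohcl_db = 0)
    out <- hi_stage(lev, l)
    if (!is.null(prev)) expect_true(all(out <= prev + 1e-15))
    prev <- out
  }
  prev <- NULL
  for (ohcl in c(0, 20, 40, 55)) {
    l <- data.frame(center_freq_hz = 1000, total_hl_db = ohcl,
                    ihcl_db = 0, ohcl_db = ohcl)
    out <- hi_stage(lev, l)
    if (!is.null(prev)) expect_true(all(out <= prev + 1e-15))
    prev <- out
  }
  expect_error(hi_stage(matrix(1, 5, 2),
                        data.frame(center_freq_hz = 1, total_hl_db = 0,
                                   ihcl_db = 0, ohcl_db = 0)),
               "per channel")
})

test_that("adaptation loops compress stationary inputs logarithmically", {
  fs <- 22050
  n <- 5L * fs
  ss <- function(level_db) {
    a <- 10^((level_db - 100) / 20)
    y <- adaptation_stage(matrix(a, n, 1), fs)
    y[n, 1]
  }
  l0 <- ss(65); l20 <- ss(85); l40 <- ss(105)
  # equal dB steps map to nearly equal output steps: ratio 0.5 +/- 0.1
  expect_lt(abs((l20 - l0) / (l40 - l0) - 0.482), 0.1)
  # zero input -> zero steady state (resting level subtracted)
  expect_lt(abs(ss(-Inf)), 1e-9)
  # onsets overshoot the steady state by > 2x
  step <- rbind(matrix(0, 2205, 1), matrix(0.1, n - 2205, 1))
  y <- adaptation_stage(step, fs)
  expect_gt(max(y) / y[n, 1], 2)
  expect_error(adaptation_stage(matrix(-1, 10, 1), fs), "nonnegative")
})

test_that("modulation stage separates modulation content by band", {
  fs2 <- 22050 / 32
  t <- (0:(round(2 * fs2) - 1)) / fs2
  # DC-only input: all bands except the lowest ~ 0
  dc <- matrix(50, length(t), 1)
  ir <- modulation_stage(dc, fs2, "fb", decimate = 1)
  steady <- ir$values[round(fs2):length(t), 1, ]
  expect_gt(mean(steady[, 1]), 45)
  expect_lt(max(abs(steady[, -1])), 1)
  # lp mode passes 4 Hz within 3 dB
  x4 <- matrix(sin(2 * pi * 4 * t), ncol = 1)
  irl <- modulation_stage(x4, fs2, "lp", decimate = 1)
  gain <- sqrt(mean(irl$values[round(fs2):length(t), 1]^2)) / sqrt(0.5)
  expect_gt(20 * log10(gain), -3)
  # 40 Hz modulation maximal in the band whose centre is nearest 40 Hz
  x40 <- matrix(100 * sin(2 * pi * 40 * t), ncol = 1)
  irf <- modulation_stage(x40, fs2, "fb", decimate = 1)
  resp <- apply(irf$values[, 1, ], 2, function(v) sqrt(mean(v^2)))
  centers <- c(0, 5, 10, 10 * (5 / 3)^(1:5))
  expect_equal(which.max(resp), which.min(abs(centers - 40)))
})

test_that("the full front-end is deterministic and NH-equivalent at zero loss", {
  sp <- speech_fixture(duration_s = 0.5)
  sp <- set_level(sp, 65)
  fb <- measure_filterbank("qc")
  ir1 <- compute_internal_representation(sp, fb, mode = "lp")
  ir2 <- compute_internal_representation(sp, fb, mode = "lp")
  expect_identical(ir1$values, ir2$values)
  ag0 <- audiogram(c(250, 8000), c(0, 0))
  ir3 <- compute_internal_representation(sp, fb, ag = ag0, mode = "lp")
  expect_identical(ir3$values, ir1$values)
  expect_true(all(is.finite(ir1$values)))
})

test_that("representation occupies the channels covering the signal band", {
  # 1 kHz tone: strong response near 1 kHz, weak far above
  fb <- measure_filterbank("psm")
  tone <- set_level(tone_signal(1000, duration_s = 0.5), 65)
  ir <- compute_internal_representation(tone, fb, mode = "lp")
  act <- apply(abs(ir$values), 2, mean)
  cfs <- fb$center_freqs_hz
  expect_gt(act[which.min(abs(cfs - 1000))], 5 * max(act[cfs > 6000]))
})
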