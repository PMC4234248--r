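test_that("map_frequency follows the power-law compression above the knee", {
  s <- nfc_settings(2000, 2)
  # identity below the knee, regardless of CR
  expect_equal(map_frequency(1000, s), 1000)
  expect_equal(map_frequency(1000, nfc_settings(2000, 10)), 1000)
  # continuity at the knee
  expect_equal(map_frequency(2000, s), 2000)
  # closed form above the knee: F_c^(1-p) F_in^p
  expect_equal(map_frequency(8000, s), sqrt(2000 * 8000))
  # CR = 1 is the identity everywhere
  grid <- seq(0, 11000, by = 50)
  expect_equal(map_frequency(grid, nfc_settings(3000, 1)), grid)
})

test_that("map_frequency is continuous, monotone, identity below knee (random triples)", {
  set.seed(101)
  for (i in 1:200) {
    fc <- stats::runif(1, 500, 8000)
    cr <- stats::runif(1, 1, 12)
    s <- nfc_settings(fc, cr)
    grid <- sort(stats::runif(60, 0, 16000))
    out <- map_frequency(grid, s)
    expect_true(all(diff(out) >= -1e-12))
    below <- grid <= fc
    expect_equal(out[below], grid[below])
    p <- 1 / cr
    expect_equal(out[!below], fc^(1 - p) * grid[!below]^p, tolerance = 1e-9)
    # continuity at the knee
    eps <- 1e-6
    expect_lt(abs(map_frequency(fc + eps, s) - map_frequency(fc - eps, s)),
              1e-3)
  }
})

test_that("nfc_process relocates tones to the mapped frequency", {
  tone <- tone_signal(8000)
  y <- nfc_process(tone, nfc_settings(2000, 2))
  bin <- 22050 / 1024
  expect_lt(abs(peak_freq(y) - 4000), bin + 1e-9)
})

test_that("nfc_process with CR = 1 is transparent", {
  sp <- speech_fixture()
  y <- nfc_process(sp, nfc_settings(3000, 1))
  # total energy conserved within 1 dB
  expect_lt(abs(10 * log10(sum(y$samples^2) / sum(sp$samples^2))), 1)
  # spectrum matches within 1 dB per third-octave band
  n <- length(sp$samples)
  A <- Mod(stats::fft(sp$samples))[1:(n %/% 2)]^2
  B <- Mod(stats::fft(y$samples))[1:(n %/% 2)]^2
  i <- 100:(n %/% 2)
  g <- floor(log2(i) * 3)
  ea <- tapply(A[i], g, sum); eb <- tapply(B[i], g, sum)
  keep <- ea > max(ea) * 1e-6      # skip empty bands
  expect_lt(max(abs(10 * log10(eb[keep] / ea[keep]))), 1)
})

test_that("nfc_process moves a noise band edge to the mapped edge", {
  set.seed(5)
  fs <- 22050
  noise <- stats::rnorm(fs)
  bf <- signal::butter(6, c(3000, 9000) / (fs / 2), type = "pass")
  nb <- audio_signal(as.numeric(signal::filter(bf, noise)), fs)
  y <- nfc_process(nb, nfc_settings(3000, 6))
  pred_edge <- map_frequency(9000, nfc_settings(3000, 6))
  sp <- Mod(stats::fft(y$samples))^2
  sm <- stats::filter(sp[1:(fs %/% 2)], rep(1 / 64, 64), sides = 2)
  pk <- max(sm[2800:3800], na.rm = TRUE)
  edge <- max(which(sm[1:5000] > pk / 4))   # -6 dB point
  bin <- fs / 1024
  expect_lt(abs(edge - 1 - pred_edge), 2 * bin)
  # no energy above the mapped Nyquist (beyond -40 dB of total)
  f_top <- map_frequency(fs / 2, nfc_settings(3000, 6)) + 2 * bin
  hi <- ceiling(f_top):(fs %/% 2)
  expect_lt(10 * log10(sum(sp[hi]) / sum(sp[1:(fs %/% 2)])), -40)
})

test_that("nfc distortion strength follows the settings ordering", {
  sp <- speech_fixture()
  lsd <- function(a, b) {
    n <- length(a$samples)
    A <- Mod(stats::fft(a$samples))[1:(n %/% 2)]^2
    B <- Mod(stats::fft(b$samples))[1:(n %/% 2)]^2
    i <- 100:(n %/% 2)
    g <- floor(log2(i) * 3)
    ea <- tapply(A[i], g, sum); eb <- tapply(B[i], g, sum)
    floor_e <- max(ea) * 1e-8
    sqrt(mean((10 * log10(pmax(eb, floor_e) / pmax(ea, floor_e)))^2))
  }
  d <- vapply(standard_nfc_settings(),
              function(s) lsd(nfc_process(sp, s), sp), numeric(1))
  expect_lt(d[["cr2-fc4k"]], d[["cr2-fc3k"]])
  expect_lt(d[["cr2-fc3k"]], d[["cr6-fc3k"]])
  expect_lt(d[["cr2-fc3k"]], d[["cr2-fc2k"]])
  # cr6 and cr10 at 3 kHz are close; require cr10 not weaker than cr6 by
  # more than 10%
  expect_gt(d[["cr10-fc3k"]], 0.9 * d[["cr6-fc3k"]])
})

test_that("nfc_process rejects a knee at or above Nyquist", {
  expect_error(nfc_process(tone_signal(1000), nfc_settings(12000, 2)),
               "Nyquist")
})

test_that("lowpass anchor matches the Butterworth magnitude contract", {
  # DC gain 1
  dc <- audio_signal(rep(0.3, 22050), 22050)
  y <- lowpass_anchor(dc)
  expect_equal(tail_rms(y$samples), 0.3, tolerance = 1e-3)
  # 3 dB at the cutoff
  t2 <- tone_signal(2000)
  a2 <- -20 * log10(tail_rms(lowpass_anchor(t2)$samples) /
                    tail_rms(t2$samples))
  expect_lt(abs(a2 - 3), 0.2)
  # >= 55 dB one octave above
  t4 <- tone_signal(4000)
  a4 <- -20 * log10(tail_rms(lowpass_anchor(t4)$samples) /
                    tail_rms(t4$samples))
  expect_gte(a4, 55)
})

test_that("clip anchor limits at the stated fraction of the observed peak", {
  sp <- speech_fixture()
  pk <- max(abs(sp$samples))
  y <- clip_anchor(sp, 0.25)
  expect_equal(max(abs(y$samples)), 0.25 * pk)
  # samples within the bound unchanged
  inside <- abs(sp$samples) <= 0.25 * pk
  expect_identical(y$samples[inside], sp$samples[inside])
  # fraction 1 is the identity
  expect_identical(clip_anchor(sp, 1)$samples, sp$samples)
  expect_error(clip_anchor(audio_signal(numeric(10) + 0, 22050)), "silent")
})

test_that("clipping a full-scale sinusoid produces strong harmonic distortion", {
  tone <- tone_signal(500, duration_s = 0.5, amp = 1)
  y <- clip_anchor(tone, 0.25)
  n <- length(y$samples)
  sp <- Mod(stats::fft(y$samples))^2
  f0_bin <- round(500 * n / 22050) + 1
  fund <- sum(sp[(f0_bin - 2):(f0_bin + 2)])
  harm <- sum(vapply(2:9, function(k) {
    b <- round(k * 500 * n / 22050) + 1
    sum(sp[(b - 2):(b + 2)])
  }, numeric(1)))
  thd <- sqrt(harm / fund)
  expect_gt(thd, 0.10)
})
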