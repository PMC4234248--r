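# ---------------------------------------------------------------------------
# Deterministic synthetic stimuli: vowel-like harmonic signals, speech-like
# sequences, the 8-condition stimulus set, and simulated MUSHRA rating
# tables.  All randomness flows from a single seed.
# ---------------------------------------------------------------------------

#' Fixture specification for synthetic speech-like signals
#'
#' @param f0_hz Fundamental frequency.
#' @param formant_freqs_hz Ascending formant frequencies (below Nyquist).
#' @param formant_bandwidths_hz Matching resonance bandwidths.
#' @param duration_s Total duration.
#' @param syllable_rate_hz Envelope modulation rate (speech syllable rate).
#' @param noise_floor_db Level of the additive noise floor relative to the
#'   signal (dB; `-Inf` disables it).
#' @param sample_rate_hz Sampling rate.
#' @param seed Integer seed fixing all randomness.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(f0_hz = 120,
                         formant_freqs_hz = c(500, 1500, 2500, 3500),
                         formant_bandwidths_hz = c(80, 100, 140, 200),
                         duration_s = 1.0, syllable_rate_hz = 4,
                         noise_floor_db = -35, sample_rate_hz = 22050,
                         seed = 1L) {
  if (is.unsorted(formant_freqs_hz, strictly = TRUE))
    stop("fixture_spec: formants must be strictly ascending")
  if (max(formant_freqs_hz) >= sample_rate_hz / 2)
    stop("fixture_spec: formants must lie below Nyquist")
  if (length(formant_freqs_hz) != length(formant_bandwidths_hz))
    stop("fixture_spec: formant frequency/bandwidth lengths differ")
  structure(list(f0_hz = f0_hz, formant_freqs_hz = formant_freqs_hz,
                 formant_bandwidths_hz = formant_bandwidths_hz,
                 duration_s = duration_s,
                 syllable_rate_hz = syllable_rate_hz,
                 noise_floor_db = noise_floor_db,
                 sample_rate_hz = sample_rate_hz,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Talker presets mirroring a 2 male + 2 female design
#'
#' Two male-like presets (f0 110 and 130 Hz, formants in the 500-3000 Hz
#' region) and two female-like presets (f0 190 and 220 Hz, formants up to
#' 4 kHz), so the second and third formants fall where frequency
#' compression interacts with vowel structure.
#'
#' @param duration_s Duration per talker fixture.
#' @param seed Base seed; each talker gets a distinct derived seed.
#' @return Named list of [fixture_spec()]s (`m1`, `m2`, `f1`, `f2`).
#' @export
talker_presets <- function(duration_s = 1.0, seed = 1L) {
  list(
    m1 = fixture_spec(110, c(550, 1100, 2400, 3100), c(70, 90, 130, 180),
                      duration_s = duration_s, seed = seed + 101L),
    m2 = fixture_spec(130, c(600, 1300, 2600, 3300), c(80, 100, 140, 190),
                      duration_s = duration_s, seed = seed + 202L),
    f1 = fixture_spec(190, c(650, 1700, 3000, 4000), c(90, 110, 150, 210),
                      duration_s = duration_s, seed = seed + 303L),
    f2 = fixture_spec(220, c(700, 1900, 3200, 4200), c(90, 120, 160, 220),
                      duration_s = duration_s, seed = seed + 404L))
}

# second-order resonator filter coefficients (pole at f, bandwidth bw)
resonator <- function(f, bw, fs) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * f / fs
  b0 <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)
  list(b = b0, a = c(1, -2 * r * cos(theta), r^2))
}

#' Generate a stationary vowel-like signal
#'
#' An impulse train at `f0_hz` (harmonic glottal source) filtered through
#' a cascade of second-order resonators at the formant frequencies, plus a
#' seeded Gaussian noise floor; deterministic for a fixed seed.
#'
#' @param spec A [fixture_spec()].
#' @return An [audio_signal()].
#' @export
make_vowel <- function(spec) {
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  src <- numeric(n)
  src[round(seq(1, n, by = fs / spec$f0_hz))] <- 1
  # gentle spectral tilt of the source (-6 dB/oct above ~500 Hz)
  a_t <- exp(-2 * pi * 500 / fs)
  src <- as.numeric(stats::filter((1 - a_t) * src, a_t, method = "recursive"))
  y <- src
  for (i in seq_along(spec$formant_freqs_hz)) {
    rf <- resonator(spec$formant_freqs_hz[i], spec$formant_bandwidths_hz[i], fs)
    y <- as.numeric(signal::filter(rf$b, rf$a, y))
  }
  if (is.finite(spec$noise_floor_db)) {
    rng <- local_rng(spec$seed)
    noise <- rng$norm(n)
    y <- y + noise * sqrt(mean(y^2)) * 10^(spec$noise_floor_db / 20) /
      sqrt(mean(noise^2))
  }
  y <- y / max(abs(y)) * 0.5
  audio_signal(y, fs)
}

#' Generate a speech-like signal
#'
#' A sequence of vowel segments (formants perturbed per segment) and soft
#' noise bursts, amplitude-modulated at the syllable rate so the envelope
#' carries realistic low-frequency modulation content.  Deterministic for
#' a fixed seed.
#'
#' @param spec A [fixture_spec()].
#' @return An [audio_signal()].
#' @export
make_speechlike <- function(spec) {
  fs <- spec$sample_rate_hz
  n <- round(spec$duration_s * fs)
  rng <- local_rng(spec$seed)
  seg_len <- round(fs / spec$syllable_rate_hz)
  nseg <- ceiling(n / seg_len)
  y <- numeric(0)
  for (s in seq_len(nseg)) {
    jitter <- 1 + 0.08 * rng$unif(length(spec$formant_freqs_hz), -1, 1)
    sp <- spec
    sp$formant_freqs_hz <- sort(spec$formant_freqs_hz * jitter)
    sp$duration_s <- seg_len / fs
    sp$noise_floor_db <- -Inf
    seg <- make_vowel(sp)$samples
    if (s %% 4 == 0) {   # occasional fricative-like burst
      burst <- rng$norm(seg_len)
      bf <- signal::butter(4, min(0.95, 2 * 3000 / fs), type = "high")
      burst <- as.numeric(signal::filter(bf, burst))
      seg <- 0.25 * burst / max(abs(burst)) * max(abs(seg))
    }
    y <- c(y, seg)
  }
  y <- y[1:n]
  # syllabic amplitude modulation (raised cosine)
  t <- (0:(n - 1)) / fs
  env <- 0.55 + 0.45 * cos(2 * pi * spec$syllable_rate_hz * t)
  y <- y * env
  if (is.finite(spec$noise_floor_db)) {
    noise <- rng$norm(n)
    y <- y + noise * sqrt(mean(y^2)) * 10^(spec$noise_floor_db / 20) /
      sqrt(mean(noise^2))
  }
  if (max(abs(y)) == 0) return(audio_signal(y + 0, fs))
  y <- y / max(abs(y)) * 0.5
  audio_signal(y, fs)
}

# seeded RNG streams that do not disturb the global RNG state
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(norm = function(n) draw(stats::rnorm, n),
       unif = function(n, a = 0, b = 1) draw(stats::runif, n, a, b))
}

#' Generate the 8-condition MUSHRA stimulus set for one reference
#'
#' The hidden reference (identity), the five standard NFC settings
#' ([standard_nfc_settings()]), the 2 kHz lowpass anchor and the
#' 25%-peak clipping anchor.
#'
#' @param ref An [audio_signal()] at the working rate.
#' @return Named list of 8 [audio_signal()]s with labels `ref`,
#'   `cr2-fc4k`, `cr2-fc3k`, `cr6-fc3k`, `cr10-fc3k`, `cr2-fc2k`, `lp`,
#'   `cl`.
#' @export
make_condition_set <- function(ref) {
  if (length(ref$samples) == 0L) stop("make_condition_set: empty reference")
  out <- list(ref = ref)
  for (nm in names(standard_nfc_settings()))
    out[[nm]] <- nfc_process(ref, standard_nfc_settings()[[nm]])
  out$lp <- lowpass_anchor(ref)
  out$cl <- clip_anchor(ref)
  out
}

#' Simulate a MUSHRA rating table from true quality scores
#'
#' Each subject's rating is a monotone (linear) map of the true score onto
#' the 0-100 scale plus i.i.d. Gaussian noise, clipped to \[0, 100\];
#' deterministic for a fixed seed.
#'
#' @param true_scores Data frame with columns `condition`, `talker`,
#'   `score`.
#' @param n_subjects Number of simulated subjects (>= 1).
#' @param noise_sd Rating noise standard deviation on the 0-100 scale.
#' @param seed Integer seed.
#' @param group Group label for the generated rows.
#' @return A `rating_table`.
#' @export
make_synthetic_ratings <- function(true_scores, n_subjects = 12,
                                   noise_sd = 5, seed = 1L,
                                   group = "NH") {
  if (n_subjects < 1) stop("make_synthetic_ratings: n_subjects must be >= 1")
  s <- true_scores$score
  rng <- if (max(s) > min(s)) (s - min(s)) / (max(s) - min(s)) else rep(0.5, length(s))
  target <- 5 + 90 * rng          # keep headroom so noise rarely clips
  gen <- local_rng(seed)
  rows <- list()
  for (subj in seq_len(n_subjects)) {
    noise <- if (noise_sd > 0) gen$norm(length(target)) * noise_sd else numeric(length(target))
    rows[[subj]] <- data.frame(
      subject = sprintf("s%02d", subj), group = group,
      condition = true_scores$condition, talker = true_scores$talker,
      rating = pmin(100, pmax(0, target + noise)),
      stringsAsFactors = FALSE)
  }
  rating_table(do.call(rbind, rows))
}

#' Write a complete fixture set to disk
#'
#' Generates the four talker fixtures, their 8-condition stimulus sets,
#' a manifest TSV (`condition`, `talker`, `ref_path`, `test_path`) and a
#' synthetic rating table TSV derived from the PSM of each pair, ready for
#' [run_benchmark()].
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param duration_s Fixture duration per talker.
#' @param n_subjects,noise_sd Passed to [make_synthetic_ratings()].
#' @return Invisibly, a list with `manifest_path` and `ratings_path`.
#' @export
write_fixture_set <- function(out_dir, seed = 17L, duration_s = 1.0,
                              n_subjects = 12, noise_sd = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- talker_presets(duration_s, seed)
  manifest <- list(); true_scores <- list()
  for (tk in names(presets)) {
    ref <- make_speechlike(presets[[tk]])
    conds <- make_condition_set(ref)
    ref_path <- file.path(out_dir, sprintf("%s_ref.wav", tk))
    write_wav(ref, ref_path)
    for (cn in names(conds)) {
      tp <- file.path(out_dir, sprintf("%s_%s.wav", tk, gsub("[^a-z0-9]", "_", cn)))
      write_wav(conds[[cn]], tp)
      manifest[[length(manifest) + 1L]] <- data.frame(
        condition = cn, talker = tk, ref_path = ref_path, test_path = tp,
        stringsAsFactors = FALSE)
      sc <- predict_quality(conds[[cn]], ref, "psm",
                            quality_options("lp"))$value
      true_scores[[length(true_scores) + 1L]] <- data.frame(
        condition = cn, talker = tk, score = sc, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  true_scores <- do.call(rbind, true_scores)
  ratings <- make_synthetic_ratings(true_scores, n_subjects, noise_sd,
                                    seed = seed + 1L)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  ratings_path <- file.path(out_dir, "ratings.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(as.data.frame(ratings), ratings_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(manifest_path = manifest_path, ratings_path = ratings_path))
}
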