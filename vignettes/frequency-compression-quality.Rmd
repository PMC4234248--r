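---
title: "Predicting the sound quality of frequency-compressed speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the sound quality of frequency-compressed speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcqual)
```

## The problem

Nonlinear frequency compression (NFC) is a hearing-aid strategy for severe
high-frequency hearing loss: spectral content above a cutoff frequency
$F_c$ is squeezed into a narrower band so that information otherwise
inaudible to the listener is moved into an audible region.  The processing
trades audibility against naturalness, and the perceived sound quality of
the result depends on the compression settings.  `fcqual` implements an
intrusive (double-ended) prediction chain for that quality: a test signal
and an unprocessed reference are passed through an auditory model, their
"internal representations" are compared, and the resulting similarity
score is correlated against MUSHRA-style subjective ratings.

## The NFC map and the anchor degradations

Below the knee the frequency map is the identity; above it, compression is
linear in log-frequency:

$$F_{out} = \begin{cases} F_{in}, & F_{in} \le F_c \\
F_c^{\,1-p}\, F_{in}^{\,p}, & F_{in} > F_c \end{cases} \qquad p = 1/CR .$$

The map is continuous and non-decreasing for every $CR \ge 1$, and
$CR = 1$ is the identity.  `nfc_process()` realises it by short-time
Fourier remapping (frame 1024, hop 256, Hann): the complex content of each
analysis bin is relocated to `map_frequency()` of its centre, split
linearly between the two nearest target bins.  Two numerical details
matter:

* **Phase propagation.** A relocated bin must advance in phase at its
  *target* frequency from frame to frame, not at its source frequency;
  each bin is therefore rotated by $e^{i 2\pi (F_{out}-F_{in}) h/f_s}$ per
  hop $h$.  Without this the overlap-add frames interfere and a pure tone
  emerges audibly (and measurably) off-frequency.
* **Output band limit.** Frame-to-frame incoherence of remapped wideband
  content leaves low-level splatter above the mapped Nyquist frequency,
  where the output should contain nothing; the final signal is therefore
  band-limited at `map_frequency(fs/2)` plus one bin.

The two MUSHRA anchors are a 10th-order Butterworth lowpass at 2 kHz
(single pass, hence −3 dB at the cutoff) and hard clipping at 25% of the
stimulus's own observed peak.  The five bundled NFC settings
(`standard_nfc_settings()`) span mild to strong compression:
$F_c$ = 4 kHz with CR 2:1, 3 kHz with CR 2:1, 6:1 and 10:1, and 2 kHz with
CR 2:1.

## The auditory front-end

`compute_internal_representation()` chains:

1. **Gammatone filterbank** — 4th-order filters, one per ERB, applied in
   the Fourier domain with the response
   $H(f) = [1 + i(f-f_c)/(1.019\,\mathrm{ERB}(f_c))]^{-4}$.  The PSM
   family analyses 235 Hz–15.3 kHz; the telephone-band qc family
   235 Hz–4 kHz.  The lower edge of the qc bank is not fixed by its
   source description ("adapted to telephone-bandpass-filtered speech");
   235 Hz is the documented, configurable default.
2. **Haircell stage** — half-wave rectification and a first-order 1 kHz
   lowpass per channel (envelope extraction).
3. **Hearing-impairment stage** (optional) — see below.
4. **Adaptation loops** — five cascaded divisive feedback loops with time
   constants 5/50/129/253/500 ms.  Stationary inputs are compressed nearly
   logarithmically (the steady-state chain response is $x^{1/32}$), onsets
   overshoot.  The input is floored at $10^{-5}$ of full scale — 0 dB SPL
   under the package's calibration convention that full-scale RMS is
   100 dB SPL — and the output rescaled to model units (silence → 0,
   stationary full scale → 100).  Overshoots are bounded by the standard
   broken-stick limiter (`overshoot_limit = 10`): without it, onset
   transients four orders of magnitude above steady state dominate the
   correlation between representations and the predicted ordering of
   processing conditions becomes erratic.
5. **Modulation analysis** — either a first-order 8 Hz lowpass per channel
   (`lp`, 2-D representation) or a modulation filterbank (`fb`, 3-D): a
   2.5 Hz lowpass, 5 Hz-wide bands at 5 and 10 Hz, then constant-Q (Q = 2)
   bands up to ≈129 Hz.  Band outputs are the real part of the complex
   band signal up to 10 Hz and its magnitude above (the usual Hilbert
   envelope convention); the bandpass path is DC-blocked.  The envelope
   path is decimated (boxcar mean, factor 32) between adaptation and
   modulation filtering, and lp-mode output a further factor 4 — frame
   rates of ≈689 Hz and ≈172 Hz, comfortably above the retained modulation
   content.

All stages are deterministic; identical inputs give bit-identical
representations.

## Hearing impairment: IHC/OHC decomposition and expansion

Given an audiogram, thresholds are interpolated to the channel centre
frequencies (linear in log-frequency, flat extrapolation) and split into
outer and inner hair-cell contributions

$$OHCL = \min(0.8 \cdot HL,\ 55\ \mathrm{dB}), \qquad IHCL = HL - OHCL,$$

the convention that OHC dysfunction carries most of a sensorineural loss
up to a cap; both parameters are arguments.  The stage inserted between
envelope extraction and adaptation operates sample by sample: amplitudes
are attenuated by IHCL dB, then passed through an expansive I/O function
driven by OHCL.  Writing instantaneous level as
$L = 100 + 20\log_{10} a$ dB,

$$L_{out} = L - OHCL\left(\frac{L_{conv} - L}{L_{conv}}\right)^{\gamma},
\qquad L < L_{conv},$$

with $L_{out} = L$ above the convergence level.  The dB-domain slope is
$\ge 1$ everywhere, largest at low levels, and decays smoothly to 1 at
$L_{conv}$ — the recruitment-like shape of an inverted compressive
cochlea.  A sample at audiometric zero is attenuated by exactly OHCL, so
attenuation plus expansion raise the simulated threshold by the full
hearing loss.  The source model states that its parameters invert Moore's
unimpaired cochlear I/O function without printing them; `fcqual`
parameterises the curve by $L_{conv}$ (default 100 dB) and $\gamma$
(default 2, any value > 1 keeps the slope continuous at the junction).
With zero loss the stage is exactly the identity, so the impaired model
with a flat 0 dB HL audiogram reproduces the normal-hearing model
bit-for-bit — a property the test suite asserts.

The same audiogram-configured model processes both test *and* reference:
the comparison is made within the simulated impaired ear.

## PSM, qc, and their options

Both measures are the overall Pearson correlation of the two complete
internal representations, flattened jointly over time, channel and (in fb
mode) modulation band.  They differ in the peripheral bandwidth (15.3 kHz
for PSM, 4 kHz for qc) and in the options applied first:

* **+B (assimilation)** — wherever the test representation falls below the
  reference the difference is halved; positive deviations are kept.
  Missing signal components are perceptually less disturbing than added
  ones.  For elementwise-attenuated test representations this never lowers
  and generically raises the score.
* **+W (band weighting)** — per-channel importance weights for the qc
  family.  The original published table is not reproduced in the source
  material, so the bundled default is a documented monotone weighting
  (unity below 1 kHz, +1 per octave above) that emphasises the higher
  telephone-band channels; alternatives can be passed explicitly.

A global correlation (rather than per-channel or frame-wise averaging) is
used deliberately: the frame-wise variant is a separate measure (PSM_t)
outside this package's scope.  Degenerate inputs follow explicit rules:
two equal constant representations score 1; a constant reference against a
non-equal test raises an error rather than returning NaN.

Because the narrowband qc model simply does not represent energy above
4 kHz, a stimulus whose degradation lives mainly above 4 kHz (e.g. a 2 kHz
lowpass) scores at least as well under qc as under PSM — the bandwidth
mechanism the test suite checks end-to-end.

## LPC-domain distances

`lpc_distance()` provides the classic narrowband measures at 8 kHz
analysis rate (32 ms Hamming frames, 16 ms hop, order 10; a 16 kHz mode
extends the band):

* **ISD** — Itakura–Saito distortion between the all-pole spectra,
  evaluated in closed form from the reference autocorrelation;
  asymmetric.
* **LLR** — log of the Toeplitz quadratic-form ratio
  $a_t^\top R_r a_t / a_r^\top R_r a_r$; asymmetric.
* **LAR** — RMS difference of log-area ratios from the reflection
  coefficients; symmetric.
* **WSSD** — Klatt's weighted comparison of critical-band log-spectral
  slopes (25 triangular Bark-spaced bands, peak-proximity weights with
  constants 20 and 1, reference/test weights averaged); symmetric and
  gain-invariant.

Frames below −60 dBFS in either signal are excluded jointly, and frames
are aggregated by a trimmed mean over the lowest 95% of distances — the
exact aggregation of the historical toolbox is not restated in the source
material, so this bound on outlier frames is a documented, configurable
default.

## The correlation harness

`run_benchmark()` mirrors the standard evaluation design: ratings are
averaged over subjects per (condition, talker) and optionally over talkers
per condition; objective scores are correlated with those means by Pearson
and Spearman coefficients (average ranks for ties), with no regression
mapping of scores.  Per-talker correlations pool all (condition × talker)
points into a single correlation.  Missing cells are dropped pairwise with
a message, never imputed.  Hidden reference and both anchors are included
by default.

## The synthetic generator

`make_speechlike()` produces harmonic vowel-like segments (impulse train
through formant resonators, −6 dB/oct source tilt) with per-segment
formant jitter, occasional highpassed noise bursts, and a 4 Hz raised-
cosine syllable envelope; two male-like (f0 110/130 Hz) and two
female-like (f0 190/220 Hz) presets mirror a 2+2 talker design, with
second and third formants in the regions where frequency compression
interacts with vowel structure (roughly 750–3000 Hz male, 1000–4000 Hz
female).  All randomness flows from a single integer seed through RNG
streams that leave the global RNG state untouched.

`make_synthetic_ratings()` maps true scores monotonically onto 5–95 on the
MUSHRA scale and adds i.i.d. Gaussian subject noise (default SD 5, 12
subjects), clipped to [0, 100].

What the generator does *not* emulate: real speech phonetics and
coarticulation, hearing-aid gain and output limiting, room and loudspeaker
acoustics, per-subject loudness adjustment, and systematic inter-subject
rating styles.  Passing tests therefore demonstrate the internal
consistency and the qualitative behaviour of the chain (ordering of
conditions, bandwidth and option effects, recovery of rating structure
from noisy data), not the published correlation magnitudes, which depend
on an unpublished subjective database.

## Numerical choices and limitations

* Working rate 22 050 Hz (covers the 15.3 kHz PSM band edge); all input
  resampled on load by Fourier-domain truncation/padding.
* Calibration: full-scale RMS ≡ 100 dB SPL, presentation level 65 dB SPL
  by default; scores are invariant to a common positive rescaling of both
  inputs.
* Alignment: broadband cross-correlation bounded to ±0.5 s, ties broken
  toward smaller |lag|; test RMS matched to reference RMS; idempotent.
* Test problem sizes: 0.8 s fixtures, 4 talkers × 8 conditions, all 16
  perception-model variants plus 4 LPC distances; the full desk benchmark
  runs in a few minutes on one CPU.
* The cr6/cr10 settings at 3 kHz are nearly equivalent for the perception
  measures (as for listeners); their relative order on any single fixture
  is not meaningful.
* The adult-like vs child-like differences in rating behaviour discussed
  in the literature are outside the model; the package predicts one score
  per (stimulus pair, measure, audiogram).

## A complete run

```{r, eval = FALSE}
sp <- make_speechlike(talker_presets()$m1)
conds <- make_condition_set(sp)
predict_quality(conds$`cr2-fc2k`, sp, "psm", quality_options("lp"))

# full benchmark against simulated ratings
dir <- tempfile()
paths <- write_fixture_set(dir, seed = 17)
manifest <- read.table(paths$manifest_path, header = TRUE, sep = "\t")
ratings <- load_ratings(paths$ratings_path)
run_benchmark(manifest, ratings)
```
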