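Package: fcqual
Title: Objective Sound Quality Prediction for Frequency-Compressed Speech
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting the perceived sound quality of
    frequency-lowered speech as produced by nonlinear frequency
    compression (NFC) hearing aids.  Provides an NFC processor and the
    standard MUSHRA anchor degradations (lowpass, peak clipping), a
    gammatone/adaptation-loop auditory model front-end with a
    hearing-impairment extension driven by an inner/outer hair cell
    decomposition of the audiogram, the internal-representation quality
    measures PSM and qc with their option variants, classic LPC-domain
    spectral distances (Itakura-Saito, log-area ratio, log-likelihood
    ratio, weighted spectral slope), and a harness that correlates
    objective scores with MUSHRA-style subjective rating tables.  A
    synthetic-stimulus module generates deterministic vowel-like test
    material and simulated rating tables so the full pipeline can be
    exercised without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
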