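Package: sbmmfecg
Title: Fetal Electrocardiogram Extraction by the Segmented-Beat Modulation Method
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extraction and denoising of fetal electrocardiograms (FECG) from
    direct (scalp) and indirect (maternal abdominal) recordings using the
    Segmented-Beat Modulation Method (SBMM), a template-based denoiser that
    splits every beat into a fixed-length QRS segment and a time-modulated
    repolarization (TU) segment so that beat-to-beat heart-rate variability is
    tracked rather than smeared. Includes zero-phase band-pass prefiltering,
    Pan-Tompkins maternal QRS detection, the two-stage abdominal extraction
    cascade (maternal ECG cancellation followed by fetal denoising),
    signal-quality metrics (beat amplitude, 4-sigma noise amplitude, SNR in dB,
    Pearson correlation, rank-sum tests, percentile summaries), a synthetic
    maternal+fetal mixture generator with exact ground truth, WFDB/CSV I/O and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
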