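Package: hfobench
Title: Benchmarking High-Frequency Oscillation Detectors on Realistic
    Simulated Stereo-EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A simulation-based validation framework for detectors of
    high-frequency oscillations (HFOs; ripples 80-250 Hz and fast ripples
    250-500 Hz) in intracerebral EEG.  Channel-specific background activity
    is modelled as an autoregressive process fitted on baseline segments and
    resynthesized from Gaussian white noise; epileptic spikes, ripples and
    fast ripples are inserted at controlled per-band signal-to-noise ratios
    with Poisson timing, spike stretching, post-spike silencing and timing
    jitter.  Five published detectors (short-time energy, short line length,
    Hilbert envelope, a wavelet-entropy baseline two-stage detector, and a
    normalized time-frequency oscillation/spike detector) are implemented
    with their published default parameters, and detections are scored
    against the inserted ground truth with 100 ms confidence intervals
    yielding sensitivity, precision, F-measure and per-class sensitivity.
    Shared machinery includes a log-scale analytic wavelet transform,
    robust per-frequency background normalization, wavelet entropy of the
    autocorrelation, and the spectral identities explaining detector biases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
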