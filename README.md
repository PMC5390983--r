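# hfobench

Simulation-based benchmarking of high-frequency-oscillation (HFO)
detectors for intracerebral EEG.

HFOs — brief oscillations at 80–250 Hz (ripples, R) and 250–500 Hz (fast
ripples, FR) — are candidate biomarkers of epileptogenic tissue, but
automatic detectors are usually validated only against visual marking,
where there is no gold standard, no control over event amplitudes, and no
way to probe robustness. `hfobench` replaces the recording with a
controlled simulation: channel-specific background activity is modelled as
an autoregressive (AR) process and resynthesized from white noise, and
epileptic spikes, ripples and fast ripples are inserted at exactly known
times and per-band signal-to-noise ratios (SNR). Because every realization
of a channel is statistically identical, changes in a detector's behaviour
across records can be attributed to the events alone.

The package provides:

* **Background models** — `estimate_ar()` (autocorrelation/LPC fit),
  `average_ar()`, `synthesize_background()`, `ar_psd()`.
* **Event dictionary** — parametric ripples/fast ripples (tapered,
  AM/FM-modulated sinusoids) and biphasic spikes, plus DWT
  coefficient-mask reconstruction (`dwt_mask_reconstruct()`) for
  extracting events from real recordings without their background.
* **Generator** — 7 event classes (Spk, Spk-R, Spk-FR, Spk-R-FR, R, FR,
  R-FR) with Poisson timing, fixed per-realization HFO SNR, random spike
  SNR, spike time-stretching, post-spike silencing and timing jitter;
  ground truth for every inserted component.
* **Five detectors** with their published default parameters: short-time
  energy (STE), short line length (SLL), Hilbert envelope (HIL), the
  two-stage wavelet-entropy/baseline detector (MNI), and a time–frequency
  detector that thresholds a robustly normalized wavelet map at 30 and
  classifies peaks as oscillations or spikes by their time width and
  frequency spread.
* **Evaluation** — 100 ms confidence-interval matching
  (`match_detections()`), sensitivity/precision/F-measure, per-class
  sensitivity, benchmark-level reports.
* **Theory helpers** — the line-length/second-difference identity, the
  `|1−e^{−jw}|⁴ = 2(3+cos 2w −4 cos w)` differencing factor, wavelet
  entropy of the autocorrelation, and PSD whitening diagnostics
  (`theory_report()`).

The detection statistic of the time–frequency detector is the normalized
energy `(z_re² + z_im²)/2`, where each frequency row of a log-scale Morlet
transform is z-scored by a Gaussian fitted to its real coefficients within
Tukey's range (quartiles ± 1.5 IQR, truncation-corrected). On pure
background these normalized coefficients are standard normal at every
frequency, which is what makes its threshold stable across SNRs.

## Worked example

```r
library(hfobench)

models <- synthetic_channel_models(1, 0)      # one quiet (low-HF) channel
dict   <- make_default_dictionary(seed = 1)   # 8 R + 8 FR + 8 spike templates
config <- sim_config(duration_s = 60, seed = 1)

chan <- generate_channel(models[[1]], dict, config,
                         snr_db = 15, realization_seed = 42)
head(chan$ground_truth[, c("event_id", "class_id", "kind", "t_center_s", "snr_db")], 4)
#>   event_id class_id kind t_center_s    snr_db
#> 1        1        2  SPK   1.459577  1.651961
#> 2        1        2    R   1.446994 15.000000
#> 3        2        4  SPK   3.532205  5.874035
#> 4        2        4    R   3.548537 15.000000

det <- hfo_detect(chan$samples, chan$fs, "delphos")
nrow(det)
#> [1] 21

m <- match_detections(chan$ground_truth, det)
unlist(compute_metrics(m))
#>      sens      prec         f
#> 0.7777778 1.0000000 0.8750000
```

The record contains 60 s of simulated background with events of all seven
classes at 3/min each; HFOs are inserted at 15 dB in their own band, spikes
at random 0–15 dB broadband. The time–frequency detector recovers 78% of
the inserted HFO components with no false positive (precision 1), and the
ground-truth table shows the per-component bookkeeping (the ripple of a
Spk-R event carries a ±20 ms jitter relative to its spike).

A thin command-line front-end (`inst/cli/hfobench.R`) exposes
`simulate`, `detect`, `evaluate` and `theory` subcommands over EDF/TSV
files for shell pipelines.

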