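---
title: "Benchmarking HFO detectors on simulated stereo-EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking HFO detectors on simulated stereo-EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

High-frequency oscillations (HFOs) — brief oscillatory events at 80–250 Hz
(ripples, R) and 250–500 Hz (fast ripples, FR) in intracerebral EEG — are
candidate biomarkers of epileptogenic tissue. Automatic HFO detectors are
usually validated against visual marking, which offers no gold standard and
no control over event rates or amplitudes. `hfobench` takes the alternative
route: it synthesizes stereo-EEG-like records in which every event is known
and every amplitude is controlled, runs a set of published detectors on
them, and scores the detections against the inserted ground truth. The
point is not only to rank detectors but to expose *why* they fail: unstable
background estimation, the 1/f spectrum, and loose HFO definitions.

## Background model

Each simulated channel's ongoing activity is an autoregressive (AR) process:
baseline stretches of a recording (or of a synthetic colored-noise target)
are fitted with the autocorrelation (Levinson–Durbin) method
(`estimate_ar()`, the classical LPC fit; `stats::ar.yw` supplies the
solver), per-segment coefficient vectors and innovation gains are averaged
per channel (`average_ar()`), and fresh realizations are drawn by filtering
Gaussian white noise through the synthesis filter
(`synthesize_background()`). Realizations from one model are statistically
identical, so any change in a detector's threshold across records is
attributable to the inserted events, not to the background.

Numerical choices: the default order is 30 at 2048 Hz (enough for the
spectral slope plus rhythmic peaks below 500 Hz); the segment mean is
removed before fitting; the innovation gain is set so the model PSD
integrates to the segment variance; a burn-in of `10 * order` samples is
discarded at synthesis; coefficient averaging is not stability-preserving,
so poles of an unstable mean are radially shrunk to modulus 0.98 (with a
warning). Note that at order 2 an unstable mean cannot occur at all (the
AR(2) stability domain is convex); it can from order 3 up.

One caveat worth knowing: the autocorrelation method is ill-conditioned
when all of a model's dynamics sit at very small normalized frequencies
(e.g. near-unit-root poles plus a ~10 Hz rhythm sampled at 2048 Hz). The
estimation-accuracy tests therefore use a classical well-conditioned AR(4)
with resonances at moderate normalized frequencies; the benchmark channels
themselves are built by pole placement and AR refitting, not by estimating
real data, so this conditioning issue does not propagate into the
benchmark.

## Synthetic channels

`synthetic_channel_models()` builds two families by fitting AR(30) to
composite targets:

* **low-HF** channels: a 1/f-like core (near-unit-root pole plus a ~10 Hz
  rhythm) over a broadband sensor floor. The 80–500 Hz band is quiet with a
  mild slope (≈ −5 to −6 dB/octave), the regime in which wavelet-entropy
  baseline detection succeeds.
* **high-HF** channels: the same core plus a strong narrow rhythm near the
  ripple/fast-ripple boundary (230–250 Hz), emulating semi-continuous
  high-frequency (SCHF) activity. Band power is elevated and rhythmic, and
  baseline detection fails — by design, since that is the behaviour the
  benchmark must reproduce.

The floor levels and rhythm strengths were chosen once so that (i) the
ripple band carries ~5–8 dB more background power than the fast-ripple band
on low-HF channels (the 1/f asymmetry that drives class-dependent
sensitivity), and (ii) the wavelet-entropy baseline fraction is comfortably
above the 5% criterion on low-HF channels and essentially zero on high-HF
channels.

## Event dictionary

The default dictionary is parametric (`make_default_dictionary()`): 8
ripples (90–220 Hz), 8 fast ripples (280–450 Hz) and 8 spikes per channel.
HFO templates are Tukey-tapered sinusoids (25% taper) with mild amplitude
modulation and frequency glides; spikes are difference-of-Gaussians
biphasic transients whose `sharpness` parameter controls the width of the
leading peak and hence the high-frequency content — sharp spikes are what
inflate SD-based detector thresholds. Cycle counts are drawn from 6–9 (R)
and 6–8 (FR), and the FR grid starts at 280 Hz: shorter or lower templates
spill more than 20% of their energy across the 250 Hz band edge and would
violate the dictionary's own in-band-energy invariant.

Templates extracted from real recordings enter through
`dwt_mask_reconstruct()`: an orthogonal periodized discrete wavelet
transform (Daubechies; db4 default, db8 available where sharper band
selectivity is needed), with a coefficient mask selecting the
time–frequency tiles of the event. Perfect reconstruction, linearity and
energy non-expansion are tested properties.

## Simulation generator

Seven event classes are supported: Spk, Spk-R, Spk-FR, Spk-R-FR, R, FR,
R-FR. Timings follow a homogeneous Poisson process at the summed class
rate (default 3/min per class); arrivals within 500 ms of one another or
within 1 s of the record edges are re-drawn, which keeps the scoring
windows of distinct events disjoint. Per realization, the HFO SNR is fixed
(grid 0/5/10/15 dB) while each spike draws a uniform SNR in 0–15 dB.

SNR is defined per band: an event is scaled so that the ratio of its mean
band-limited power over its support to the background's mean power in the
same band equals the target (ripple band 80–250 Hz, fast-ripple band
250–500 Hz, spikes broadband 1–500 Hz since they are not band-limited).
Both powers are measured with the same zero-phase FIR filter. At 0 dB an
event is amplitude-matched to the background.

Spikes are stretched in time by a uniform factor in (0.8, 1.25), and the
background is multiplied by a raised-cosine notch dipping to
`1 − silencing_depth` (default 0.5) over the spike support — post-spike
silencing, a deliberate source of non-stationarity. HFOs co-occurring with
a spike or another HFO receive an independent uniform timing jitter of
±20 ms. HFOs are added after all spikes so the silencing notch never
attenuates them.

One design choice matters for interpretation: realization seeds are shared
across SNRs, so the same background, timeline and spike draws recur at
every SNR and only the HFO amplitudes differ. Threshold drifts and
sensitivity changes across the SNR grid are then paired comparisons.

## Detectors

Four time-domain detectors share an 80–500 Hz zero-phase FIR front-end
(Blackman-windowed, > 60 dB stopband); the published default parameters are
frozen as named constants:

* **STE** — 3 ms RMS trace; threshold mean + 5 SD; segments merged over
  10 ms gaps, minimum 6 ms; kept only with more than 6 rectified peaks
  above mean + 3 SD.
* **SLL** — line length of the first-differenced, band-passed signal over a
  12 ms window; threshold at the 97.5th percentile; minimum duration 12 ms.
  The differencing-plus-line-length pipeline is identical to a rectified
  moving sum of the second difference, whose gain
  `2(3 + cos 2w − 4 cos w)` grows monotonically with frequency — the
  analytic reason this detector over-expresses fast ripples.
* **HIL** — analytic-signal envelope; threshold 5 SD of the whole-record
  envelope (the published wording; a flag adds the mean term for the
  STE-style reading, under which the detector finds no true HFO below
  10 dB on this benchmark and its low-SNR sensitivity consists only of
  spike coincidences); minimum 10 ms. An essentially constant envelope
  (CV < 5%) yields no detections.
* **MNI** — two stages. Stage 1 computes, per 125 ms window, the wavelet
  entropy (WE) of the window's autocorrelation; windows with WE at or above
  0.67 of the theoretical maximum *and* without large transients are
  baseline (the amplitude guard mirrors the original detector's multiple
  baseline criteria; without it a single spike — impulse-like, hence
  high-entropy — would poison the percentile below). With ≥ 5% baseline,
  the threshold is the 99.9999th percentile of the baseline RMS
  distribution (on finite samples effectively a maximum order statistic;
  the interpolation convention follows `stats::quantile`'s default).
  Otherwise the STE-style threshold is iterated, removing detected events
  from the estimate (≤ 10 iterations). Stage 2 is the STE machinery with a
  10 ms minimum duration and no peak-count criterion, as in the original
  two-stage detector.
* **Time–frequency detector** (threshold 30) — runs on the raw signal. A
  log-scale analytic Morlet transform (10–512 Hz, 12 voices/octave,
  `omega0 = 6`) is normalized per frequency row by a Gaussian fitted to the
  real coefficients within Tukey's range (quartiles ± 1.5 IQR), with the
  SD corrected for truncation by the analytic factor 0.9714 (SD of a
  standard normal truncated at ±2.698σ). Local maxima of the normalized
  energy `(z_re² + z_im²)/2` above 30 are classified by comparing their
  half-height time width and frequency spread against self-calibrated
  references — a Dirac impulse's time width and a pure tone's frequency
  spread per row, computed once per sampling rate. A peak is an oscillation
  if its frequency spread stays below 1.4× the tone reference while its
  time width exceeds 1.4× the impulse reference; the converse pattern is a
  spike. Oscillation detections at 80–500 Hz are the HFO output; only they
  enter benchmark scoring.

All detectors exclude the first and last 0.5 s of a record (filter and
circular-CWT edge effects) and are deterministic.

## Wavelet entropy conventions

The printed definition of the continuous wavelet transform leaves the
scale prefactor ambiguous, and the choice matters for the entropy:

* the detection transform (`cwt_logscale()`) peak-normalizes each row's
  frequency response, so a unit tone yields unit magnitude at every
  frequency — oscillations have comparable footprints along the log axis;
* the entropy transform (`wavelet_entropy()`) L2-normalizes its rows
  (equal impulse-response energy). Under this convention a white-noise
  window (delta-like autocorrelation) scores near the theoretical maximum
  `log10(|A|)` and a mildly sloped background stays above the 0.67
  baseline criterion, while rhythmic windows concentrate onto few scales
  and score low. With peak normalization, white noise itself would sit
  ~40% below the maximum and the baseline criterion would be meaningless.

The scale set uses 4 voices per octave over 80–500 Hz (11 scales). A
coarser one-per-octave set makes the entropy of any distribution too
granular: with three scales, no convention separates sloped-but-eventless
backgrounds (which must count as baseline) from rhythmic SCHF activity
(which must not).

The estimated per-frequency background power divides the fitted σ² by the
row's squared-response bandwidth: a constant-Q bank's row variance scales
as PSD(f) × bandwidth(f), and the division makes the estimate track the AR
spectrum up to one global offset (verified to within 2 dB in the tests).

## Scoring

A 100 ms confidence interval (CI) is centred on every inserted HFO
component; spikes get none, so spike-triggered detections count as false
positives — deliberately. A detection matches a CI if their intervals
overlap; each detection is assigned to at most one CI (nearest centre);
a matched CI is one TP regardless of how many detections fall inside
(surplus detections are neither TP nor FP); unmatched CIs are FN and
unassigned detections FP. Sens = TP/(TP+FN), Prec = TP/(TP+FP),
F = 2PS/(P+S). When a detector makes no detections at all, precision (and
F) are reported as missing rather than imputed. Per-class sensitivity
treats composite classes per component: Spk-R-FR contributes one R CI and
one FR CI. CIs of distinct events can never overlap (generator spacing);
overlap across events is treated as a configuration error, while
co-occurring components of one composite event overlap by design.

## Problem sizes

The bundled benchmark used by the acceptance tests and script is
4 channels (2 low-HF, 2 high-HF) × {0, 5, 10, 15} dB × 5 realizations of
120 s at 2048 Hz — 80 records, ~40 events per record. The rate contract is
checked over 30 one-minute timelines, and the normalization contract on a
single 60 s background. `make_fixture_benchmark()` also offers `tiny`
(1 × 2 × 2 × 60 s) and `paper` (8 × 4 × 30 × 600 s) scales; the latter is
provided for completeness and takes correspondingly longer.

## What the simulation does and does not show

The generator reproduces the properties the detectors are sensitive to:
patient- and region-specific spectra (via AR models), 1/f-induced
amplitude asymmetry between ripples and fast ripples, sharp-spike
outliers, post-spike silencing, co-occurring and jittered events, and
controlled per-band SNR. It does not model non-stationary background
drifts, spatially correlated multichannel noise, artifacts or line noise,
chirping HFOs with strong frequency modulation, or posterior-region
activity. Passing benchmarks here therefore demonstrates robustness to the
modelled phenomena only; clinical performance additionally depends on the
unmodelled ones.

## Known limitations

* The evaluation treats any detection overlapping a CI as a hit; a
  detector that fires on the spike of a Spk-R event is credited with the
  ripple. This mirrors the scoring rule's simplicity, and is visible in
  non-zero sensitivities at 0 dB where the HFOs themselves are invisible.
* The AR fit degrades for processes whose dynamics are concentrated at
  very low normalized frequencies (see above).
* The time–frequency detector's width-based classification misses strongly
  chirping events (a "comma-shaped" blob fails the width test); ridge-based
  width estimation would be the natural extension.
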