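# The five detectors on constructed scenarios.

burst_in_bkg <- function(f0, n_cycles, snr_db, t_s = 30, dur = 60,
                         seed = 11, amp = NULL) {
  bkg <- synthesize_background(fx_low_model(), dur, seed = seed)
  tpl <- make_synthetic_hfo(f0, n_cycles)
  w <- if (is.null(amp)) as.numeric(scale_to_snr(tpl, bkg, snr_db))
  else amp * tpl$waveform
  hfobench:::add_waveform(bkg, w, t_s, fx_fs)
}

test_that("STE detects a strong 8-cycle ripple and reports its threshold", {
  x <- burst_in_bkg(150, 8, 20)
  d <- detect_ste(x, fx_fs)
  hits <- abs(d$t_peak_s - 30) < 0.05
  expect_identical(sum(hits), 1L)
  expect_gt(attr(d, "threshold"), 0)
})

test_that("STE rejects a 2-cycle burst via the rectified-peak criterion", {
  # 2 cycles at 150 Hz lasts 13.3 ms (> 6 ms duration gate) but cannot
  # contain more than 6 qualifying rectified peaks
  bkg <- synthesize_background(fx_low_model(), 60, seed = 13)
  tpl_ref <- make_synthetic_hfo(150, 8)
  g <- attr(scale_to_snr(tpl_ref, bkg, 20), "gain")
  short <- sin(2 * pi * 150 * (0:round(2 / 150 * fx_fs)) / fx_fs) *
    hfobench:::tukey_window(round(2 / 150 * fx_fs) + 1, 0.25)
  x <- hfobench:::add_waveform(bkg, g * short, 30, fx_fs)
  d <- detect_ste(x, fx_fs)
  expect_identical(sum(abs(d$t_peak_s - 30) < 0.05), 0L)
})

test_that("STE null behavior on pure background is quiet", {
  d <- detect_ste(fx_background(), fx_fs)
  expect_lt(nrow(d), 5)    # count recorded as a bound, not an exact value
})

test_that("SLL energy trace is the windowed second difference identity", {
  expect_lt(sll_second_diff_equivalence(with_seed(4, rnorm(5000)), 25L),
            1e-10)
  d <- detect_sll(rep(1, 30 * fx_fs) + 0, fx_fs)
  expect_identical(nrow(d), 0L)
})

test_that("a fast ripple outruns an equal-SNR ripple in SLL energy", {
  bkg <- synthesize_background(fx_low_model(), 60, seed = 15)
  x <- bkg
  x <- hfobench:::add_waveform(
    x, as.numeric(scale_to_snr(make_synthetic_hfo(120, 8), bkg, 10)), 20, fx_fs)
  x <- hfobench:::add_waveform(
    x, as.numeric(scale_to_snr(make_synthetic_hfo(400, 8), bkg, 10)), 40, fx_fs)
  x1 <- c(0, diff(x))
  filt <- bandpass_80_500(x1, fx_fs)
  e <- hfobench:::moving_mean(c(0, abs(diff(filt))), 25) * 25
  peak_at <- function(t) max(e[(round(t * fx_fs) - 150):(round(t * fx_fs) + 150)])
  expect_gt(peak_at(40), peak_at(20))
})

test_that("HIL applies the 10 ms duration gate", {
  mk <- function(dur_ms) {
    bkg <- synthesize_background(fx_low_model(), 60, seed = 17)
    n <- round(dur_ms / 1000 * fx_fs)
    ref <- as.numeric(scale_to_snr(make_synthetic_hfo(300, 8), bkg, 20))
    burst <- sin(2 * pi * 250 * (0:(n - 1)) / fx_fs) * max(abs(ref))
    hfobench:::add_waveform(bkg, burst, 30, fx_fs)
  }
  d_long <- detect_hil(mk(14), fx_fs)
  expect_gte(sum(abs(d_long$t_peak_s - 30) < 0.05), 1L)
  d_short <- detect_hil(mk(6), fx_fs)
  expect_identical(sum(abs(d_short$t_peak_s - 30) < 0.05), 0L)
})

test_that("an unmodulated tone yields no HIL detections and no crash", {
  tone <- sin(2 * pi * 150 * (0:(20 * fx_fs - 1)) / fx_fs)
  d <- detect_hil(tone, fx_fs)
  expect_identical(nrow(d), 0L)
})

test_that("a large spike inflates the HIL threshold", {
  bkg <- synthesize_background(fx_low_model(), 60, seed = 19)
  thr0 <- attr(detect_hil(bkg, fx_fs), "threshold")
  spk <- fx_dictionary()$SPK[[8]]
  x <- insert_spike(bkg, spk, 30, k = 0.85, snr_db = 15, silencing_depth = 0)
  thr1 <- attr(detect_hil(as.numeric(x), fx_fs), "threshold")
  expect_gt(thr1, thr0)
})

test_that("MNI selects baseline mode on quiet channels, no-baseline on SCHF", {
  b_low <- synthesize_background(fx_low_model(), 60, seed = 23)
  d_low <- detect_mni(b_low, fx_fs)
  expect_identical(attr(d_low, "mode"), "baseline")
  b_high <- synthesize_background(fx_high_model(), 60, seed = 23)
  d_high <- detect_mni(b_high, fx_fs)
  expect_identical(attr(d_high, "mode"), "no_baseline")
  expect_error(detect_mni(rnorm(5 * fx_fs), fx_fs), "10 s")
})

test_that("baseline mode is more precise than forced no-baseline on noise", {
  x <- bandpass_80_500(with_seed(29, rnorm(60 * fx_fs)), fx_fs)
  d_base <- detect_mni(x, fx_fs, force_mode = "baseline")
  d_iter <- detect_mni(x, fx_fs, force_mode = "no_baseline")
  expect_lte(nrow(d_base), nrow(d_iter))
})

test_that("iterative MNI threshold drops as events are removed", {
  bkg <- synthesize_background(fx_high_model(), 60, seed = 27)
  x <- bkg
  for (t in c(10, 20, 30, 40, 50)) {
    w <- as.numeric(scale_to_snr(make_synthetic_hfo(140, 9), bkg, 20))
    x <- hfobench:::add_waveform(x, w, t, fx_fs)
  }
  d <- detect_mni(x, fx_fs, force_mode = "no_baseline")
  filt <- bandpass_80_500(x, fx_fs)
  rms <- sqrt(hfobench:::moving_mean(filt^2, round(0.003 * fx_fs)))
  reg <- hfobench:::detection_region(length(x), fx_fs)
  rr <- rms[reg[1]:reg[2]]
  thr_initial <- mean(rr) + 5 * sd(rr)
  expect_lt(attr(d, "threshold"), thr_initial)
})

test_that("Delphos classifies the calibration archetypes correctly", {
  bkg <- synthesize_background(fx_low_model(), 20, seed = 33)
  tone_burst <- as.numeric(scale_to_snr(make_synthetic_hfo(200, 10), bkg, 25))
  x <- hfobench:::add_waveform(bkg, tone_burst, 10, fx_fs)
  d <- detect_delphos(x, fx_fs, all_types = TRUE)
  near <- d[abs(d$t_peak_s - 10) < 0.05, ]
  expect_true(any(near$type == "oscillation" &
                    abs(near$peak_freq_hz - 200) < 50))
  spike <- fx_dictionary()$SPK[[8]]
  x2 <- insert_spike(bkg, spike, 10, k = 1, snr_db = 15, silencing_depth = 0)
  d2 <- detect_delphos(as.numeric(x2), fx_fs, all_types = TRUE)
  near2 <- d2[abs(d2$t_peak_s - 10) < 0.08, ]
  expect_gt(nrow(near2), 0)
  expect_false(any(near2$type == "oscillation" & near2$peak_freq_hz >= 80 &
                     near2$peak_freq_hz <= 500))
})

test_that("pure background stays below the Delphos threshold", {
  n_osc <- sapply(1:8, function(s) {
    x <- synthesize_background(fx_low_model(), 30, seed = 600 + s)
    nrow(detect_delphos(x, fx_fs))
  })
  expect_gte(mean(n_osc == 0), 0.95)
})

test_that("a 15 dB fast ripple riding a spike is still detected", {
  bkg <- synthesize_background(fx_low_model(), 30, seed = 35)
  spike <- fx_dictionary()$SPK[[3]]
  x <- as.numeric(insert_spike(bkg, spike, 15, k = 1, snr_db = 12,
                               silencing_depth = 0.5))
  fr <- as.numeric(scale_to_snr(make_synthetic_hfo(350, 7), bkg, 15))
  x <- hfobench:::add_waveform(x, fr, 15.012, fx_fs)
  d <- detect_delphos(x, fx_fs)
  expect_true(any(abs(d$t_peak_s - 15.012) < 0.05 & d$peak_freq_hz > 250))
})

test_that("detectors are deterministic and share the dispatcher", {
  x <- burst_in_bkg(150, 8, 15, t_s = 15, seed = 41, dur = 30)
  for (m in c("ste", "sll", "hil", "delphos")) {
    d1 <- hfo_detect(x, fx_fs, m)
    d2 <- hfo_detect(x, fx_fs, m)
    expect_identical(d1, d2)
  }
})
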