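# Event timeline, SNR scaling, spike insertion, channel assembly.

test_that("Poisson event counts match the configured rate", {
  cfg <- sim_config(class_rates = c(0, 0, 0, 0, 3, 0, 0), duration_s = 3600)
  tl <- draw_event_timeline(cfg, seed = 8)
  expect_true(all(tl$class_id == 5))
  expect_lt(abs(nrow(tl) - 180), 3 * sqrt(180))
})

test_that("timelines are deterministic, spaced and edge-guarded", {
  cfg <- sim_config(duration_s = 300)
  tl1 <- draw_event_timeline(cfg, seed = 4)
  tl2 <- draw_event_timeline(cfg, seed = 4)
  expect_identical(tl1, tl2)
  expect_gte(min(diff(tl1$t_s)), 0.5)
  expect_gte(min(tl1$t_s), 1)
  expect_lte(max(tl1$t_s), 300 - 1)
  expect_error(draw_event_timeline(sim_config(duration_s = 1.5), 1),
               "too short")
  expect_error(draw_event_timeline(sim_config(class_rates = rep(0, 7)), 1),
               "rate")
})

test_that("SNR scaling hits the requested in-band power ratio", {
  bkg <- fx_background()
  tpl <- fx_dictionary()$R[[2]]
  p_b <- band_power(bkg, tpl$band, fx_fs)
  w0 <- scale_to_snr(tpl, bkg, 0)
  expect_equal(band_power(as.numeric(w0), tpl$band, fx_fs) / p_b, 1,
               tolerance = 0.02)
  w10 <- scale_to_snr(tpl, bkg, 10)
  expect_equal(band_power(as.numeric(w10), tpl$band, fx_fs) / p_b, 10,
               tolerance = 0.05 * 10)
  # scale equivariance: doubling the background doubles the scaled event
  w2 <- scale_to_snr(tpl, 2 * bkg, 10)
  expect_equal(attr(w2, "gain") / attr(w10, "gain"), 2, tolerance = 1e-6)
  expect_error(scale_to_snr(tpl, bkg[1:1000], 0), "5 s")
})

test_that("spike insertion: silencing, stretch and pure-addition limits", {
  bkg <- fx_background()[1:(20 * fx_fs)]
  spk <- fx_dictionary()$SPK[[4]]
  out0 <- insert_spike(bkg, spk, 10, k = 1, snr_db = 10, silencing_depth = 0)
  d <- as.numeric(out0) - bkg
  sup <- attr(out0, "support")
  expect_true(all(d[-(sup[1]:sup[2])] == 0))
  expect_equal(d[sup[1]:sup[2]],
               attr(out0, "gain") * hfobench:::stretch_waveform(spk$waveform, 1),
               tolerance = 1e-12)
  out1 <- insert_spike(bkg, spk, 10, k = 1, snr_db = 10, silencing_depth = 1)
  mid <- round(mean(attr(out1, "support")))
  g <- attr(out1, "gain")
  wmid <- hfobench:::stretch_waveform(spk$waveform, 1)[mid - attr(out1, "support")[1] + 1]
  # the notch minimum falls between samples for even supports, leaving a
  # residual background term of order sin^2(pi / (2 n))
  expect_equal(as.numeric(out1)[mid], g * wmid, tolerance = 1e-4)
  # stretch factor doubles the duration measured at 10% of peak
  dur_at <- function(k) {
    w <- hfobench:::stretch_waveform(spk$waveform, k)
    sum(abs(w) > 0.1 * max(abs(w))) / fx_fs
  }
  expect_equal(dur_at(2) / dur_at(1), 2, tolerance = 0.05)
  expect_error(insert_spike(bkg, spk, 0.01, 1, 10, 0), "outside")
})

test_that("generate_channel respects class composition and determinism", {
  cfg <- sim_config(class_rates = c(3, 0, 0, 0, 0, 0, 0), duration_s = 60,
                    seed = 2)
  ch <- generate_channel(fx_low_model(), fx_dictionary(), cfg, 10, 77)
  expect_true(all(ch$ground_truth$kind == "SPK"))
  ch2 <- generate_channel(fx_low_model(), fx_dictionary(), cfg, 10, 77)
  expect_identical(ch$samples, ch2$samples)
  expect_identical(ch$ground_truth, ch2$ground_truth)
})

test_that("with zero rates the channel is the bare background realization", {
  cfg <- sim_config(class_rates = rep(0, 7), duration_s = 30)
  ch <- generate_channel(fx_low_model(), fx_dictionary(), cfg, 10, 55)
  bkg <- synthesize_background(fx_low_model(), 30,
                               seed = derive_seed(55, "bkg"))
  expect_identical(ch$samples, bkg)
  expect_identical(nrow(ch$ground_truth), 0L)
})

test_that("re-measured SNR of every inserted HFO is within 1 dB of target", {
  cfg <- sim_config(duration_s = 60, seed = 31)
  snr <- 15
  ch <- generate_channel(fx_low_model(), fx_dictionary(), cfg, snr, 91)
  bkg <- synthesize_background(fx_low_model(), 60,
                               seed = derive_seed(91, "bkg"))
  hf <- ch$ground_truth[ch$ground_truth$kind %in% c("R", "FR"), ]
  expect_gt(nrow(hf), 5)
  # event-free twin realization isolates each event's added waveform
  # single-HFO classes away from spikes: the added waveform is exactly one
  # scaled template
  clean_classes <- hf$class_id %in% c(5, 6)
  for (i in which(clean_classes)) {
    band <- hfobench:::band_for_kind(hf$kind[i])
    p_b <- band_power(bkg, band, fx_fs)
    i0 <- round(hf$t_center_s[i] * fx_fs)
    halfwin <- round(0.1 * fx_fs)
    seg <- (ch$samples - bkg)[(i0 - halfwin):(i0 + halfwin)]
    # isolate this event's support within the window
    nz <- which(seg != 0)
    meas <- band_power(seg[min(nz):max(nz)], band, fx_fs) / p_b
    expect_lt(abs(10 * log10(meas) - snr), 1)
  }
})

test_that("event-free twin comparison recovers the 15 dB power ratio", {
  cfg <- sim_config(class_rates = c(0, 0, 0, 0, 3, 0, 0), duration_s = 60,
                    seed = 5)
  ch <- generate_channel(fx_low_model(), fx_dictionary(), cfg, 15, 13)
  bkg <- synthesize_background(fx_low_model(), 60,
                               seed = derive_seed(13, "bkg"))
  hf <- ch$ground_truth[ch$ground_truth$kind == "R", ]
  ratios <- sapply(seq_len(nrow(hf)), function(i) {
    i0 <- round(hf$t_center_s[i] * fx_fs)
    diffsig <- (ch$samples - bkg)
    nz <- which(diffsig != 0 & abs(seq_along(diffsig) - i0) < 0.15 * fx_fs)
    band_power(diffsig[min(nz):max(nz)], c(80, 250), fx_fs) /
      band_power(bkg, c(80, 250), fx_fs)
  })
  expect_true(all(abs(ratios / 10^1.5 - 1) < 0.2))
})

test_that("benchmark generation writes a complete deterministic tree", {
  dir1 <- tempfile("bench")
  cfg <- sim_config(duration_s = 20, n_realizations = 3,
                    snr_grid_db = c(5, 15), seed = 9,
                    class_rates = c(3, 0, 0, 0, 3, 3, 0))
  mf <- generate_benchmark(fx_models(), fx_dictionary(), cfg, dir1)
  edfs <- list.files(dir1, pattern = "\\.edf$", recursive = TRUE)
  expect_length(edfs, 2 * 2 * 3)
  dir2 <- tempfile("bench")
  generate_benchmark(fx_models(), fx_dictionary(), cfg, dir2)
  tsv1 <- sort(list.files(dir1, pattern = "_events\\.tsv$", recursive = TRUE))
  for (f in tsv1) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
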