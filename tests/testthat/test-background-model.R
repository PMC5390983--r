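# AR background module: estimation, averaging, synthesis, spectra.

test_that("white noise yields near-zero AR coefficients and gain = SD", {
  x <- with_seed(7, rnorm(2^16, sd = 3))
  fit <- estimate_ar(baseline_segment(x, fx_fs, "w"), order = 8)
  expect_lt(max(abs(fit$coeffs)), 0.05)
  expect_equal(fit$gain, sd(x), tolerance = 0.02)
})

test_that("known AR(4) is recovered within 2% at n = 2^18", {
  m <- fx_ar4()
  x <- synthesize_background(m, 2^18 / fx_fs, seed = 3)
  fit <- estimate_ar(baseline_segment(x, fx_fs, "ar4"), order = 4)
  expect_lt(max(abs(fit$coeffs - m$coeffs) / abs(m$coeffs)), 0.02)
})

test_that("degenerate segments are rejected", {
  expect_error(estimate_ar(baseline_segment(rep(1, 5000), fx_fs, "c"), 8),
               "zero variance")
  expect_error(estimate_ar(baseline_segment(rnorm(5000), fx_fs, "s"), 1000),
               "too short")
  expect_error(baseline_segment(rnorm(100), fx_fs), "shorter than 2 s")
  expect_error(baseline_segment(c(rnorm(5000), NA), fx_fs), "NA/Inf")
})

test_that("averaging AR models is the element-wise mean and idempotent", {
  m <- estimate_ar(baseline_segment(with_seed(1, rnorm(8192)), fx_fs, "a"), 6)
  expect_identical(average_ar(list(m)), m)
  avg <- average_ar(list(m, m))
  expect_equal(avg$coeffs, m$coeffs)
  expect_equal(avg$gain, m$gain)
  m2 <- m; m2$channel_id <- "b"
  expect_error(average_ar(list(m, m2)), "different channels")
  m3 <- estimate_ar(baseline_segment(with_seed(1, rnorm(8192)), fx_fs, "a"), 4)
  expect_error(average_ar(list(m, m3)), "mixed orders")
  expect_error(average_ar(list()), "empty")
})

test_that("unstable coefficient means are stabilized by pole shrinkage", {
  # the AR stability region in coefficient space is convex at order 2 but
  # not at order 3; this stable pair (found by pole placement) has an
  # unstable mean (pole modulus 1.007)
  m1 <- hfobench:::new_ar_model("c", c(-2.423597, 2.292327, -0.805782), 1, fx_fs)
  m2 <- hfobench:::new_ar_model("c", c(-1.598897, 1.393193, -0.366470), 1, fx_fs)
  expect_true(hfobench:::ar_is_stable(m1))
  expect_true(hfobench:::ar_is_stable(m2))
  mean_model <- hfobench:::new_ar_model("c", (m1$coeffs + m2$coeffs) / 2,
                                        1, fx_fs)
  expect_false(hfobench:::ar_is_stable(mean_model))
  expect_warning(avg <- average_ar(list(m1, m2)), "shrinking poles")
  expect_true(hfobench:::ar_is_stable(avg))
  expect_lte(max(Mod(ar_poles(avg))), 0.98 + 1e-8)
})

test_that("order-0 synthesis is white noise at the innovation gain", {
  m <- hfobench:::new_ar_model("w", numeric(0), 2.5, fx_fs)
  x <- synthesize_background(m, 30, seed = 5)
  expect_length(x, 30 * fx_fs)
  expect_equal(sd(x), 2.5, tolerance = 0.02)
})

test_that("synthesized backgrounds match the theoretical AR spectrum", {
  m <- fx_ar4()
  x <- synthesize_background(m, 120, seed = 9)
  p <- welch_psd(x, fx_fs, nfft = 8192)
  bands <- cbind(c(1, 4, 16, 64, 250), c(4, 16, 64, 250, 500))
  dev_db <- apply(bands, 1, function(b) {
    sel <- p$freq_hz >= b[1] & p$freq_hz < b[2]
    10 * log10(mean(p$power[sel]) / mean(ar_psd(m, p$freq_hz[sel])))
  })
  # shape agreement: band-averaged deviation from a single global offset
  expect_lt(max(abs(dev_db - mean(dev_db))), 1)
})

test_that("distinct seeds give uncorrelated realizations; same seed repeats", {
  m <- fx_ar4()
  x1 <- synthesize_background(m, 30, seed = 1)
  x2 <- synthesize_background(m, 30, seed = 2)
  expect_lt(abs(cor(x1, x2)), 0.05)
  expect_identical(x1, synthesize_background(m, 30, seed = 1))
})

test_that("ar_psd matches closed forms", {
  m0 <- hfobench:::new_ar_model("w", numeric(0), 3, fx_fs)
  expect_equal(ar_psd(m0, c(0, 100, 500)), rep(9, 3))
  m1 <- hfobench:::new_ar_model("a", -0.9, 1, fx_fs)
  ratio <- ar_psd(m1, 0) / ar_psd(m1, fx_fs / 2 - 1e-9)
  expect_equal(ratio, ((1 + 0.9) / (1 - 0.9))^2, tolerance = 1e-6)
  expect_error(ar_psd(m1, fx_fs / 2), "fs/2")
})

test_that("synthesized background is stationary across 5 s windows", {
  x <- synthesize_background(fx_ar4(), 50, seed = 71)
  v <- sapply(split(x, rep(1:10, each = 5 * fx_fs)), var)
  expect_lt(max(abs(v - mean(v)) / mean(v)), 0.2)
})

test_that("realizations from one model are statistically identical (KS)", {
  # amplitude samples are thinned to the process decorrelation scale so the
  # two-sample KS test sees approximately independent draws
  m <- fx_ar4()
  thin <- seq(1, 5 * fx_fs, by = 64)
  pass <- logical(100)
  for (i in 1:100) {
    a <- synthesize_background(m, 5, seed = 1000 + i)[thin]
    b <- synthesize_background(m, 5, seed = 2000 + i)[thin]
    pass[i] <- suppressWarnings(ks.test(a, b)$p.value) > 0.01
  }
  expect_gte(mean(pass), 0.95)
})

test_that("estimate/synthesize round trip preserves the PSD within 1 dB", {
  m <- fx_ar4()
  x <- synthesize_background(m, 120, seed = 21)
  fit <- estimate_ar(baseline_segment(x, fx_fs, "ar4"), order = m$order)
  f <- seq(1, 500, by = 1)
  bands <- cbind(c(1, 4, 16, 64, 250), c(4, 16, 64, 250, 500))
  d <- apply(bands, 1, function(b) {
    sel <- f >= b[1] & f < b[2]
    10 * log10(mean(ar_psd(fit, f[sel])) / mean(ar_psd(m, f[sel])))
  })
  expect_lt(max(abs(d)), 1)
})

test_that("AR model JSON round trip", {
  m <- fx_low_model()
  path <- tempfile(fileext = ".json")
  write_ar_model(m, path)
  m2 <- read_ar_model(path)
  expect_equal(m2$coeffs, m$coeffs)
  expect_equal(m2$gain, m$gain)
  expect_identical(m2$channel_id, m$channel_id)
})
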