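# Confidence-interval matching and metric computation.

test_that("the 100 ms CI boundary is exercised correctly", {
  gt <- gt_row(10)
  inside <- det_row(10.044, 10.054)   # peak 49 ms from centre, overlaps CI
  m <- match_detections(gt, inside)
  expect_identical(c(m$TP, m$FP, m$FN), c(1L, 0L, 0L))
  outside <- det_row(10.075, 10.085)  # 80 ms from centre, no overlap
  m2 <- match_detections(gt, outside)
  expect_identical(c(m2$TP, m2$FP, m2$FN), c(0L, 1L, 1L))
})

test_that("no detections means all CIs are misses", {
  m <- match_detections(gt_row(seq(5, 50, by = 5)), hfobench:::empty_detections())
  expect_identical(c(m$TP, m$FP, m$FN), c(0L, 0L, 10L))
  expect_identical(compute_metrics(m)$sens, 0)
  expect_true(is.na(compute_metrics(m)$prec))
})

test_that("spikes never receive CIs; surplus detections are not FPs", {
  gt <- rbind(gt_row(10), gt_row(20, kind = "SPK", class_id = 1, event_id = 2))
  det <- rbind(det_row(9.98, 10.00), det_row(10.01, 10.03),  # both in CI
               det_row(19.99, 20.01))                        # on the spike
  m <- match_detections(gt, det)
  expect_identical(c(m$TP, m$FP, m$FN), c(1L, 1L, 0L))
})

test_that("matching equals the brute-force oracle on random instances", {
  set.seed(99)
  for (trial in 1:1000) {
    n_ci <- sample(0:8, 1)
    centers <- if (n_ci) sort(runif(n_ci, 1, 60)) else numeric(0)
    while (n_ci > 1 && min(diff(centers)) < 0.5)
      centers <- sort(runif(n_ci, 1, 60))
    gt <- gt_row(centers, event_id = seq_len(n_ci))
    n_d <- sample(0:8, 1)
    lo <- runif(n_d, 0, 60)
    det <- det_row(lo, lo + runif(n_d, 0.005, 0.08))
    m <- match_detections(gt, det)
    bf <- brute_force_counts(gt, det)
    expect_identical(c(TP = m$TP, FP = m$FP, FN = m$FN), bf)
  }
})

test_that("metric arithmetic follows the definitions", {
  m <- list(TP = 15, FN = 15, FP = 5)
  met <- compute_metrics(m)
  expect_equal(met$sens, 0.5)
  expect_equal(met$prec, 0.75)
  expect_equal(met$f, 0.6)
  expect_equal(unlist(compute_metrics(list(TP = 30, FN = 0, FP = 0))),
               c(sens = 1, prec = 1, f = 1))
  met0 <- compute_metrics(list(TP = 0, FN = 10, FP = 3))
  expect_equal(met0$sens, 0)
  expect_equal(met0$prec, 0)
  expect_equal(met0$f, 0)
  expect_error(compute_metrics(list(TP = -1, FN = 0, FP = 0)), "negative")
})

test_that("per-class sensitivity splits composites per component", {
  gt <- rbind(gt_row(10, "R", 5, 1), gt_row(20, "FR", 6, 2),
              gt_row(30, "R", 7, 3), gt_row(30.01, "FR", 7, 3))
  det <- rbind(det_row(9.99, 10.01), det_row(29.99, 30.00))
  m <- match_detections(gt, det)
  pc <- per_class_sensitivity(m)
  expect_equal(pc$sensitivity[pc$class_id == 5], 1)
  expect_equal(pc$sensitivity[pc$class_id == 6], 0)
  expect_equal(pc$sensitivity[pc$class_id == 7], 0.5)
  expect_true(is.na(pc$sensitivity[pc$class_id == 2]))  # no inserted events
  # CI-count-weighted class sensitivities reproduce the overall sensitivity
  ok <- !is.na(pc$sensitivity)
  expect_equal(sum(pc$sensitivity[ok] * pc$n_ci[ok]) / sum(pc$n_ci[ok]),
               compute_metrics(m)$sens)
})

test_that("an R-band-only detector scores 1 on R classes, 0 on FR classes", {
  gt <- rbind(gt_row(c(10, 40), "R", c(2, 5), 1:2),
              gt_row(c(20, 50), "FR", c(3, 6), 3:4))
  det <- det_row(c(9.99, 39.99), c(10.01, 40.01))
  pc <- per_class_sensitivity(match_detections(gt, det))
  expect_equal(pc$sensitivity[pc$class_id %in% c(2, 5)], c(1, 1))
  expect_equal(pc$sensitivity[pc$class_id %in% c(3, 6)], c(0, 0))
})

test_that("counts are invariant to detection order; outside FP adds one", {
  gt <- gt_row(c(10, 20, 30))
  det <- rbind(det_row(9.99, 10.01), det_row(19.96, 19.97),
               det_row(29.99, 30.02))
  m1 <- match_detections(gt, det)
  m2 <- match_detections(gt, det[c(3, 1, 2), ])
  expect_identical(c(m1$TP, m1$FP, m1$FN), c(m2$TP, m2$FP, m2$FN))
  m3 <- match_detections(gt, rbind(det, det_row(45, 45.02)))
  expect_identical(m3$FP, m1$FP + 1L)
  expect_identical(m3$TP, m1$TP)
})

test_that("overlapping CIs across distinct events are a hard error", {
  gt <- gt_row(c(10, 10.05), event_id = 1:2)
  expect_error(match_detections(gt, det_row(9, 9.1)), "spacing violated")
  # same event: allowed (composite class with jitter)
  gt2 <- gt_row(c(10, 10.05), kind = c("R", "FR"), class_id = 7,
                event_id = c(1, 1))
  expect_silent(match_detections(gt2, det_row(9, 9.1)))
})

test_that("benchmark report counts rows and scores a perfect detector", {
  mk_rec <- function(det, chan, snr, real, gt, dd)
    list(channel = chan, snr_db = snr, realization = real, detector = det,
         ground_truth = gt, detections = dd, threshold = 1)
  results <- list()
  for (det in c("a", "b")) for (snr in c(5, 15)) for (r in 1:3) {
    gt <- gt_row(c(10, 20, 30), event_id = 1:3)
    dd <- det_row(c(9.99, 19.99, 29.99), c(10.01, 20.01, 30.01))
    results[[length(results) + 1]] <- mk_rec(det, "c1", snr, r, gt, dd)
  }
  rep <- benchmark_report(results)
  expect_identical(nrow(rep$records), 12L)
  expect_true(all(rep$records$sens == 1))
  expect_true(all(rep$records$prec == 1))
  expect_true(all(rep$by_snr$f == 1))
  out <- tempfile("report")
  write_report(rep, out)
  expect_true(all(file.exists(file.path(out, c("metrics.tsv", "per_class.tsv",
                                               "thresholds.tsv",
                                               "summary.json")))))
})
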