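# Small constructors and the brute-force matching oracle shared by the
# evaluation and acceptance suites.

gt_row <- function(t, kind = "R", class_id = 5, event_id = seq_along(t)) {
  if (!length(t))
    return(data.frame(event_id = integer(0), class_id = integer(0),
                      kind = character(0), t_center_s = numeric(0),
                      snr_db = numeric(0), k = numeric(0),
                      jitter_s = numeric(0)))
  data.frame(event_id = event_id, class_id = class_id, kind = kind,
             t_center_s = t, snr_db = 10, k = 1, jitter_s = 0)
}

det_row <- function(lo, hi) {
  if (!length(lo)) return(hfobench:::empty_detections())
  data.frame(detector = "x", t_start_s = lo, t_end_s = hi,
             t_peak_s = (lo + hi) / 2, type = "oscillation",
             peak_freq_hz = NA_real_, score = 1)
}

# independent oracle: CIs are disjoint, so TP = #CIs overlapped by >= 1
# detection and FP = #detections overlapping no CI
brute_force_counts <- function(gt, det, ci_ms = 100) {
  half <- ci_ms / 2000
  hfo <- gt[gt$kind %in% c("R", "FR"), ]
  n_tp <- 0L
  for (i in seq_len(nrow(hfo))) {
    lo <- hfo$t_center_s[i] - half; hi <- hfo$t_center_s[i] + half
    if (any(det$t_start_s < hi & det$t_end_s > lo)) n_tp <- n_tp + 1L
  }
  n_fp <- 0L
  for (d in seq_len(nrow(det))) {
    ov <- any(det$t_start_s[d] < hfo$t_center_s + half &
                det$t_end_s[d] > hfo$t_center_s - half)
    if (!ov) n_fp <- n_fp + 1L
  }
  c(TP = n_tp, FP = n_fp, FN = nrow(hfo) - n_tp)
}

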