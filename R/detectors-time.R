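# The four time-domain detectors (STE, SLL, HIL, MNI), with the published
# default parameters frozen as named constants.

# Window lengths / gates from the detectors' original publications (RIPPLELAB
# defaults): STE 3 ms RMS window, 6 ms minimum duration (3 periods at
# 500 Hz), >6 rectified peaks above mean+3SD, 10 ms merge gap; SLL 12 ms
# window and duration, 97.5th percentile; HIL 5 SD envelope, 10 ms minimum;
# MNI 125 ms baseline windows, 99.9999th baseline percentile, 10 ms duration.
STE_RMS_WINDOW_S <- 0.003
STE_MIN_DURATION_S <- 0.006
STE_RMS_SD_FACTOR <- 5
STE_PEAK_SD_FACTOR <- 3
STE_MIN_PEAKS <- 6            # "more than 6 peaks"
STE_MERGE_GAP_S <- 0.010
SLL_WINDOW_S <- 0.012
SLL_MIN_DURATION_S <- 0.012
SLL_PERCENTILE <- 0.975
HIL_SD_FACTOR <- 5
HIL_MIN_DURATION_S <- 0.010
MNI_BASELINE_WINDOW_S <- 0.125
MNI_BASELINE_PERCENTILE <- 0.999999
MNI_MIN_DURATION_S <- 0.010
MNI_WE_FRACTION <- 0.67       # baseline if WE >= fraction of theoretical max
MNI_MIN_BASELINE_FRAC <- 0.05
MNI_MAX_ITER <- 10L
EDGE_EXCLUSION_S <- 0.5       # filter/CWT edge effects excluded everywhere

# samples eligible for detection (edges excluded)
detection_region <- function(n, fs) {
  e <- round(EDGE_EXCLUSION_S * fs)
  c(e + 1L, n - e)
}

runs_to_detections <- function(runs, fs, metric, detector, type = "unspecified",
                               score_offset = 0L) {
  if (is.null(runs) || nrow(runs) == 0L) return(empty_detections())
  do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs[i, "start"]; i1 <- runs[i, "end"]
    pk <- i0 - 1L + which.max(metric[i0:i1])
    data.frame(detector = detector, t_start_s = (i0 - 1) / fs,
               t_end_s = i1 / fs, t_peak_s = (pk - 1) / fs, type = type,
               peak_freq_hz = NA_real_, score = metric[pk],
               stringsAsFactors = FALSE)
  }))
}

# supra-threshold runs within the detection region, merged and duration-gated
threshold_runs <- function(metric, thr, fs, min_dur_s, merge_gap_s = 0) {
  n <- length(metric)
  reg <- detection_region(n, fs)
  mask <- metric > thr
  mask[seq_len(reg[1] - 1L)] <- FALSE
  if (reg[2] < n) mask[(reg[2] + 1L):n] <- FALSE
  runs <- logical_runs(mask)
  if (nrow(runs) == 0L) return(runs)
  if (merge_gap_s > 0) runs <- merge_runs(runs, round(merge_gap_s * fs))
  runs[runs[, "end"] - runs[, "start"] + 1L >= round(min_dur_s * fs), ,
       drop = FALSE]
}

#' Short Time Energy (STE) detector
#'
#' Moving RMS (3 ms) of the 80-500 Hz band-passed signal; segments above
#' `mean + 5 SD` of the RMS trace, merged over 10 ms gaps and lasting at
#' least 6 ms, are kept if they contain more than 6 rectified-signal peaks
#' above `mean + 3 SD` of the rectified trace.
#'
#' @param x Raw signal (band-passing is applied internally).
#' @param fs Sampling rate (Hz).
#' @return Detection data.frame (`detector`, `t_start_s`, `t_end_s`,
#'   `t_peak_s`, `type`, `peak_freq_hz`, `score`) with the RMS threshold as
#'   attribute `"threshold"`.
#' @export
detect_ste <- function(x, fs) {
  filt <- bandpass_80_500(x, fs)
  rms <- sqrt(moving_mean(filt^2, round(STE_RMS_WINDOW_S * fs)))
  reg <- detection_region(length(x), fs)
  rr <- rms[reg[1]:reg[2]]
  thr <- mean(rr) + STE_RMS_SD_FACTOR * stats::sd(rr)
  rect <- abs(filt)
  rc <- rect[reg[1]:reg[2]]
  thr_pk <- mean(rc) + STE_PEAK_SD_FACTOR * stats::sd(rc)
  runs <- threshold_runs(rms, thr, fs, STE_MIN_DURATION_S, STE_MERGE_GAP_S)
  if (nrow(runs)) {
    keep <- vapply(seq_len(nrow(runs)), function(i) {
      seg <- rect[runs[i, "start"]:runs[i, "end"]]
      if (length(seg) < 3L) return(FALSE)
      m <- seg[2:(length(seg) - 1)]
      peaks <- m > seg[1:(length(seg) - 2)] & m >= seg[3:length(seg)] &
        m > thr_pk
      sum(peaks) > STE_MIN_PEAKS
    }, TRUE)
    runs <- runs[keep, , drop = FALSE]
  }
  out <- runs_to_detections(runs, fs, rms, "ste", "oscillation")
  attr(out, "threshold") <- thr
  out
}

#' Short Line Length (SLL) detector
#'
#' First-order backward differencing, 80-500 Hz band-pass, then the line
#' length over a 12 ms sliding window. The threshold is the 97.5th
#' percentile of the empirical distribution of the line-length trace over
#' the record; detections must last at least 12 ms. The differencing plus
#' line-length pipeline is equivalent to a rectified moving sum of the
#' second difference, which over-expresses high frequencies (see
#' [second_diff_psd_factor()]).
#'
#' @inheritParams detect_ste
#' @return Detection data.frame with attribute `"threshold"`.
#' @export
detect_sll <- function(x, fs) {
  x1 <- c(0, diff(x))
  filt <- bandpass_80_500(x1, fs)
  w <- round(SLL_WINDOW_S * fs)
  ll <- c(0, abs(diff(filt)))
  e <- moving_mean(ll, w) * w               # centered moving sum
  reg <- detection_region(length(x), fs)
  thr <- stats::quantile(e[reg[1]:reg[2]], SLL_PERCENTILE, names = FALSE)
  runs <- threshold_runs(e, thr, fs, SLL_MIN_DURATION_S)
  out <- runs_to_detections(runs, fs, e, "sll", "oscillation")
  attr(out, "threshold") <- thr
  out
}

#' Hilbert envelope (HIL) detector
#'
#' Magnitude of the analytic signal of the 80-500 Hz band-passed record;
#' supra-threshold stretches of the envelope above `5 SD` of the whole
#' record's envelope lasting at least 10 ms are detections. An
#' essentially constant envelope (coefficient of variation below 5%, e.g.
#' an unmodulated tone) carries no detectable events and returns none.
#'
#' @inheritParams detect_ste
#' @param add_mean If `TRUE`, threshold at `mean + 5 SD` instead of the
#'   plain `5 SD` reading.
#' @return Detection data.frame with attribute `"threshold"`.
#' @export
detect_hil <- function(x, fs, add_mean = FALSE) {
  filt <- bandpass_80_500(x, fs)
  env <- Mod(analytic_signal(filt))
  reg <- detection_region(length(x), fs)
  ev <- env[reg[1]:reg[2]]
  s <- stats::sd(ev)
  if (!is.finite(s) || s < 0.05 * mean(ev)) {
    out <- empty_detections()
    attr(out, "threshold") <- Inf
    return(out)
  }
  thr <- if (add_mean) mean(ev) + HIL_SD_FACTOR * s else HIL_SD_FACTOR * s
  runs <- threshold_runs(env, thr, fs, HIL_MIN_DURATION_S)
  out <- runs_to_detections(runs, fs, env, "hil", "oscillation")
  attr(out, "threshold") <- thr
  out
}

#' MNI two-stage detector
#'
#' Stage 1 segments the record into 125 ms windows and computes the wavelet
#' entropy of each window's autocorrelation; windows whose entropy exceeds
#' a fraction (default 0.67) of the theoretical maximum are baseline. If
#' baseline covers at least 5% of the record, the energy threshold is the
#' 99.9999th percentile of the RMS trace over baseline windows; otherwise
#' ("no baseline" mode, typical of channels with semi-continuous
#' high-frequency activity) the threshold is optimized by iteratively
#' removing previously detected events from the estimate.
#'
#' @inheritParams detect_ste
#' @param we_fraction Baseline wavelet-entropy criterion, as a fraction of
#'   the theoretical maximum entropy.
#' @param min_baseline_frac Minimum baseline share for baseline mode.
#' @param force_mode `"auto"` (default) selects the mode from the baseline
#'   fraction; `"baseline"`/`"no_baseline"` force a stage-2 variant (used
#'   for diagnostics).
#' @return Detection data.frame with attributes `"threshold"`, `"mode"`
#'   (`"baseline"` or `"no_baseline"`) and `"baseline_fraction"`.
#' @export
detect_mni <- function(x, fs, we_fraction = MNI_WE_FRACTION,
                       min_baseline_frac = MNI_MIN_BASELINE_FRAC,
                       force_mode = c("auto", "baseline", "no_baseline")) {
  force_mode <- match.arg(force_mode)
  if (length(x) < 10 * fs)
    stop("record shorter than 10 s: baseline statistics undefined",
         call. = FALSE)
  filt <- bandpass_80_500(x, fs)
  rms <- sqrt(moving_mean(filt^2, round(STE_RMS_WINDOW_S * fs)))
  wlen <- round(MNI_BASELINE_WINDOW_S * fs)
  reg <- detection_region(length(x), fs)
  starts <- seq(reg[1], reg[2] - wlen + 1L, by = wlen)
  we <- vapply(starts, function(s) {
    win <- filt[s:(s + wlen - 1L)]
    if (all(win == 0)) return(0)
    wavelet_entropy(win, fs)$S
  }, 1)
  s_max <- log10(length(we_scales()))
  # baseline windows need high entropy AND no large transient: the original
  # two-stage detector excludes candidate-event segments from its baseline
  # set; an epileptic spike is impulse-like (white-like autocorrelation) and
  # would otherwise pass the entropy criterion and poison the percentile
  amp_cap <- stats::median(rms[reg[1]:reg[2]]) +
    5 * stats::mad(rms[reg[1]:reg[2]])
  wmax <- vapply(starts, function(s) max(rms[s:(s + wlen - 1L)]), 1)
  is_base <- we >= we_fraction * s_max & wmax <= amp_cap
  base_frac <- mean(is_base)
  use_baseline <- switch(force_mode,
                         auto = base_frac >= min_baseline_frac,
                         baseline = TRUE, no_baseline = FALSE)
  if (use_baseline && !any(is_base))
    stop("no baseline windows found; cannot force baseline mode",
         call. = FALSE)
  if (use_baseline) {
    mode <- "baseline"
    idx <- unlist(lapply(starts[is_base], function(s) s:(s + wlen - 1L)))
    thr <- stats::quantile(rms[idx], MNI_BASELINE_PERCENTILE, names = FALSE)
  } else {
    mode <- "no_baseline"
    rr <- rms[reg[1]:reg[2]]
    keep <- rep(TRUE, length(rr))
    thr <- mean(rr) + STE_RMS_SD_FACTOR * stats::sd(rr)
    for (it in seq_len(MNI_MAX_ITER)) {
      det <- rr > thr
      # widen removed stretches to the full candidate segments
      runs <- logical_runs(det)
      if (nrow(runs)) {
        for (i in seq_len(nrow(runs)))
          keep[max(1, runs[i, "start"] - wlen %/% 4):
                 min(length(rr), runs[i, "end"] + wlen %/% 4)] <- FALSE
      }
      thr_new <- mean(rr[keep]) + STE_RMS_SD_FACTOR * stats::sd(rr[keep])
      if (!is.finite(thr_new) || abs(thr_new - thr) < 1e-3 * thr) break
      thr <- thr_new
    }
  }
  runs <- threshold_runs(rms, thr, fs, MNI_MIN_DURATION_S, STE_MERGE_GAP_S)
  out <- runs_to_detections(runs, fs, rms, "mni", "oscillation")
  attr(out, "threshold") <- thr
  attr(out, "mode") <- mode
  attr(out, "baseline_fraction") <- base_frac
  out
}
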