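# Time-frequency oscillation/spike detector on the normalized wavelet map:
# local maxima of the robustly normalized energy above a fixed threshold are
# classified by comparing their time width and frequency spread against
# self-calibrated references (a pure tone's frequency spread, a Dirac
# impulse's time width).

DELPHOS_THRESHOLD <- 30       # normalized energy threshold
DELPHOS_F_MIN <- 10
DELPHOS_F_MAX <- 512
DELPHOS_VOICES <- 12
DELPHOS_RATIO <- 1.4          # osc/spike classification ratio vs references

# Self-calibration: half-height time width of an impulse and half-height
# frequency spread (in octaves) of a grid tone, per frequency row.
# Cached per (fs, grid).
.delphos_cal_cache <- new.env(parent = emptyenv())

half_height_extent <- function(v, peak_idx) {
  h <- v[peak_idx] / 2
  lo <- peak_idx
  while (lo > 1L && v[lo - 1L] > h) lo <- lo - 1L
  hi <- peak_idx
  while (hi < length(v) && v[hi + 1L] > h) hi <- hi + 1L
  c(lo, hi)
}

delphos_calibration <- function(fs) {
  key <- sprintf("%g", fs)
  if (!is.null(.delphos_cal_cache[[key]])) return(.delphos_cal_cache[[key]])
  n <- round(2 * fs)
  imp <- numeric(n); imp[n %/% 2] <- 1
  tf_i <- cwt_logscale(imp, fs, DELPHOS_F_MIN, DELPHOS_F_MAX, DELPHOS_VOICES)
  E_i <- Mod(tf_i$coefficients)^2
  freqs <- tf_i$freqs_hz
  imp_width_s <- vapply(seq_along(freqs), function(i) {
    ext <- half_height_extent(E_i[i, ], n %/% 2)
    (ext[2] - ext[1] + 1) / fs
  }, 1)
  tone_spread_oct <- vapply(seq_along(freqs), function(i) {
    tone <- sin(2 * pi * freqs[i] * (0:(n - 1)) / fs)
    tf_t <- cwt_logscale(tone, fs, DELPHOS_F_MIN, DELPHOS_F_MAX,
                         DELPHOS_VOICES)
    col <- Mod(tf_t$coefficients[, n %/% 2])^2
    ext <- half_height_extent(col, which.max(col))
    (ext[2] - ext[1] + 1) / DELPHOS_VOICES
  }, 1)
  cal <- list(freqs = freqs, imp_width_s = imp_width_s,
              tone_spread_oct = tone_spread_oct)
  .delphos_cal_cache[[key]] <- cal
  cal
}

#' Time-frequency (Delphos-style) oscillation and spike detector
#'
#' Runs on the raw, unfiltered signal. The log-scale analytic wavelet map is
#' normalized per frequency by a Gaussian fitted within Tukey's range
#' ([zh0_normalize()]); local maxima of the normalized energy above 30 are
#' measured for time width (half-height extent along the peak's frequency
#' row) and frequency spread (half-height extent across rows). A peak is an
#' oscillation if its frequency spread is similar to the wavelet's own
#' (ratio < 1.4) and its time width clearly exceeds a Dirac impulse's
#' (ratio > 1.4); the converse pattern is a spike. Oscillation detections
#' with peak frequency in 80-500 Hz constitute the HFO output.
#'
#' @param x Raw signal (at least 2 s).
#' @param fs Sampling rate (Hz).
#' @param threshold Normalized-energy threshold (default 30).
#' @param all_types If `TRUE`, return spike and unclassified peaks too;
#'   default returns only 80-500 Hz oscillation detections.
#' @return Detection data.frame (`detector`, `t_start_s`, `t_end_s`,
#'   `t_peak_s`, `type`, `peak_freq_hz`, `score`); attribute `"threshold"`.
# Normalized-energy map in time-major (time x frequency) layout: contiguous
# column writes and per-row vector stats keep long records fast.
delphos_energy <- function(x, fs) {
  n <- length(x)
  n_oct <- log2(DELPHOS_F_MAX / DELPHOS_F_MIN)
  k <- 0:floor(n_oct * DELPHOS_VOICES)
  freqs <- DELPHOS_F_MIN * 2^(k / DELPHOS_VOICES)
  X <- stats::fft(x)
  fgrid <- (0:(n - 1)) * fs / n
  npos <- sum(fgrid <= fs / 2)
  Et <- matrix(0, n, length(freqs))
  qsub <- if (n > 2^16) seq(1L, n, by = 4L) else seq_len(n)
  for (i in seq_along(freqs)) {
    fa <- freqs[i]
    half <- 13 * fa / MORLET_OMEGA0
    j <- max(2L, ceiling((fa - half) * n / fs)):
      min(npos, floor((fa + half) * n / fs) + 1L)
    H <- exp(-0.5 * MORLET_OMEGA0^2 * ((fgrid[j] - fa) / fa)^2)
    Xi <- complex(length.out = n)
    Xi[j] <- X[j] * (2 * H)
    row <- stats::fft(Xi, inverse = TRUE) / n
    re <- Re(row); im <- Im(row)
    q <- stats::quantile(re[qsub], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    if (iqr <= 0)
      stop(sprintf("degenerate coefficient row at %.1f Hz (zero IQR)",
                   fa), call. = FALSE)
    keep <- re >= q[1] - 1.5 * iqr & re <= q[2] + 1.5 * iqr
    mu <- mean(re[keep])
    sigma <- stats::sd(re[keep]) / TUKEY_TRUNC_SD
    mu_im <- mean(im[keep])
    Et[, i] <- ((re - mu)^2 + (im - mu_im)^2) / (2 * sigma^2)
  }
  list(Et = Et, freqs = freqs)
}

#' @export
detect_delphos <- function(x, fs, threshold = DELPHOS_THRESHOLD,
                           all_types = FALSE) {
  if (length(x) < 2 * fs)
    stop("record shorter than 2 s: normalization unstable", call. = FALSE)
  assert_numeric_signal(x)
  em <- delphos_energy(x, fs)
  Et <- em$Et                          # time x frequency
  freqs <- em$freqs
  cal <- delphos_calibration(fs)
  n <- nrow(Et)
  nf <- ncol(Et)
  reg <- detection_region(n, fs)
  cand <- which(Et > threshold, arr.ind = TRUE)   # col 1 = time, col 2 = freq
  cand <- cand[cand[, 1] >= reg[1] & cand[, 1] <= reg[2], , drop = FALSE]
  out <- empty_detections()
  if (nrow(cand)) {
    is_max <- vapply(seq_len(nrow(cand)), function(i) {
      c0 <- cand[i, 1]; r <- cand[i, 2]
      v <- Et[c0, r]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c0 + dc
        if (rr >= 1 && rr <= nf && cc >= 1 && cc <= n && Et[cc, rr] > v)
          return(FALSE)
      }
      TRUE
    }, TRUE)
    cand <- cand[is_max, , drop = FALSE]
  }
  if (nrow(cand)) {
    dets <- lapply(seq_len(nrow(cand)), function(i) {
      c0 <- cand[i, 1]; r <- cand[i, 2]
      text <- half_height_extent(Et[, r], c0)
      width_s <- (text[2] - text[1] + 1) / fs
      fext <- half_height_extent(Et[c0, ], r)
      spread_oct <- (fext[2] - fext[1] + 1) / DELPHOS_VOICES
      rt <- width_s / cal$imp_width_s[r]
      rf <- spread_oct / cal$tone_spread_oct[r]
      type <- if (rf < DELPHOS_RATIO && rt > DELPHOS_RATIO) "oscillation"
      else if (rf >= DELPHOS_RATIO && rt <= DELPHOS_RATIO) "spike"
      else "unspecified"
      data.frame(detector = "delphos", t_start_s = (text[1] - 1) / fs,
                 t_end_s = text[2] / fs, t_peak_s = (c0 - 1) / fs,
                 type = type, peak_freq_hz = freqs[r], score = Et[c0, r],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, dets)
    # one event can culminate in several neighbouring maxima; keep the
    # strongest of any overlapping detections within half an octave
    out <- out[order(-out$score), ]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      if (i < nrow(out)) {
        j <- (i + 1):nrow(out)
        dup <- keep[j] &
          out$t_start_s[j] < out$t_end_s[i] &
          out$t_end_s[j] > out$t_start_s[i] &
          abs(log2(out$peak_freq_hz[j] / out$peak_freq_hz[i])) <= 0.5
        keep[j][dup] <- FALSE
      }
    }
    out <- out[keep, ]
    out <- out[order(out$t_peak_s), ]
    if (!all_types)
      out <- out[out$type == "oscillation" & out$peak_freq_hz >= 80 &
                   out$peak_freq_hz <= 500, ]
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- threshold
  out
}

match_row <- function(f, freqs) which.min(abs(freqs - f))

#' Run a named detector
#'
#' Dispatcher over the five detectors.
#' @param x Raw signal.
#' @param fs Sampling rate (Hz).
#' @param method One of `"ste"`, `"sll"`, `"hil"`, `"mni"`, `"delphos"`.
#' @param ... Passed to the detector.
#' @return Detection data.frame.
#' @export
hfo_detect <- function(x, fs, method = c("ste", "sll", "hil", "mni",
                                         "delphos"), ...) {
  method <- match.arg(method)
  switch(method,
         ste = detect_ste(x, fs, ...),
         sll = detect_sll(x, fs, ...),
         hil = detect_hil(x, fs, ...),
         mni = detect_mni(x, fs, ...),
         delphos = detect_delphos(x, fs, ...))
}
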