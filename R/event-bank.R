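# Event dictionary: parametric synthetic HFOs and epileptic spikes, plus
# template validation. Extraction from real recordings goes through
# dwt_mask_reconstruct(); the parametric path keeps the framework fully
# self-contained.

#' Event template
#'
#' A finite waveform with class label and native band; the dictionary atom
#' the generator inserts into simulated background.
#'
#' @param waveform Numeric vector, zero-mean.
#' @param fs Sampling rate (Hz).
#' @param kind `"SPK"`, `"R"` or `"FR"`.
#' @param source Free-text provenance (parameters or extraction origin).
#' @return An `event_template` with fields `waveform`, `fs`, `kind`, `band`,
#'   `duration_s`, `source`.
#' @export
event_template <- function(waveform, fs, kind, source = "") {
  assert_numeric_signal(waveform, "waveform")
  kind <- match.arg(kind, c("SPK", "R", "FR"))
  band <- band_for_kind(kind, fs)
  tpl <- structure(list(waveform = waveform - mean(waveform), fs = fs,
                        kind = kind, band = band,
                        duration_s = length(waveform) / fs, source = source),
                   class = "event_template")
  validate_event_template(tpl)
  tpl
}

#' Validate an event template
#'
#' Checks zero mean, and for R/FR that at least 80% of the waveform energy
#' lies inside the class band (measured with the package band-pass filter)
#' and that the duration covers at least 4 cycles at the dominant frequency.
#' @param tpl An `event_template`.
#' @return The template, invisibly; errors on violation.
#' @export
validate_event_template <- function(tpl) {
  stopifnot(inherits(tpl, "event_template"))
  w <- tpl$waveform
  if (abs(mean(w)) > 1e-8 * stats::sd(w))
    stop("template waveform is not zero-mean", call. = FALSE)
  if (tpl$kind %in% c("R", "FR")) {
    inband <- band_power(w, tpl$band, tpl$fs)
    total <- mean(w^2)
    if (inband < 0.8 * total)
      stop(sprintf("%s template has only %.0f%% of its energy in %g-%g Hz",
                   tpl$kind, 100 * inband / total, tpl$band[1], tpl$band[2]),
           call. = FALSE)
    f0 <- dominant_frequency(w, tpl$fs)
    if (tpl$duration_s < 4 / f0)
      stop(sprintf("%s template shorter than 4 cycles at %.0f Hz",
                   tpl$kind, f0), call. = FALSE)
  }
  invisible(tpl)
}

# Dominant frequency via zero-padded periodogram.
dominant_frequency <- function(w, fs) {
  nfft <- max(4096L, 2^ceiling(log2(length(w))))
  X <- Mod(stats::fft(c(w, numeric(nfft - length(w)))))[1:(nfft / 2)]
  (which.max(X) - 1) * fs / nfft
}

#' Synthetic HFO template
#'
#' Tukey-tapered sinusoid of `n_cycles / f0` seconds with optional slow
#' amplitude modulation and a linear-in-log frequency glide, emulating the
#' amplitude/frequency modulation seen in recorded HFOs.
#'
#' @param f0 Centre frequency, 80-500 Hz. `f0 < 250` gives a ripple (R),
#'   otherwise a fast ripple (FR).
#' @param n_cycles Number of cycles (>= 4).
#' @param fs Sampling rate (Hz).
#' @param am_depth Amplitude-modulation depth in `[0, 1]` (0 = none).
#' @param fm_semitones Total frequency glide in semitones, geometrically
#'   centred on `f0` (0 = none).
#' @param seed Seed for the modulation phase draw.
#' @return An `event_template` of kind `"R"` or `"FR"`, unit peak amplitude.
#' @export
make_synthetic_hfo <- function(f0, n_cycles = 6, fs = 2048, am_depth = 0,
                               fm_semitones = 0, seed = 1) {
  if (f0 < 80 || f0 > 500)
    stop("'f0' must lie in 80-500 Hz", call. = FALSE)
  if (n_cycles < 4) stop("'n_cycles' must be >= 4", call. = FALSE)
  dur <- n_cycles / f0
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  f_inst <- f0 * 2^(fm_semitones / 12 * (t / dur - 0.5))
  phase <- 2 * pi * cumsum(c(0, f_inst[-n])) / fs
  x <- sin(phase)
  if (am_depth > 0) {
    phi <- with_seed(seed, stats::runif(1, 0, 2 * pi))
    x <- x * (1 - am_depth * (0.5 + 0.5 * sin(2 * pi * t / dur + phi)))
  }
  x <- x * tukey_window(n, 0.25)
  x <- x - mean(x)
  x <- x / max(abs(x))
  event_template(x, fs, if (f0 < 250) "R" else "FR",
                 source = sprintf("synthetic f0=%g n_cycles=%g am=%g fm=%g",
                                  f0, n_cycles, am_depth, fm_semitones))
}

#' Synthetic epileptic spike template
#'
#' Biphasic transient from the difference-of-Gaussians family: a sharp
#' positive deflection followed by a slower wave of opposite sign.
#' `sharpness` narrows the leading peak, which raises its high-frequency
#' content (the mechanism by which sharp spikes create outliers in
#' energy-based detector statistics). Unit peak amplitude, zero mean.
#'
#' @param width_ms Total support, 20-200 ms.
#' @param sharpness Sharpness factor >= 1.
#' @param fs Sampling rate (Hz).
#' @param seed Unused placeholder kept for interface symmetry.
#' @return An `event_template` of kind `"SPK"`.
#' @export
make_synthetic_spike <- function(width_ms = 60, sharpness = 2, fs = 2048,
                                 seed = 1) {
  if (width_ms < 20 || width_ms > 200)
    stop("'width_ms' must lie in 20-200 ms", call. = FALSE)
  if (sharpness < 1) stop("'sharpness' must be >= 1", call. = FALSE)
  w <- width_ms / 1000
  n <- round(w * fs)
  t <- (seq_len(n) - 1) / fs - w / 3          # sharp peak in the first third
  s1 <- 0.0075 / sharpness                    # leading peak width (s)
  s2 <- w / 5                                 # slow wave width
  x <- exp(-0.5 * (t / s1)^2) -
    (s1 / s2) * exp(-0.5 * ((t - w / 6) / s2)^2)
  x <- x * tukey_window(n, 0.4)
  x <- x - mean(x)
  x <- x / max(abs(x))
  if (max(x) < 1) x <- -x                     # positive-going main peak
  event_template(x, fs, "SPK",
                 source = sprintf("synthetic width_ms=%g sharpness=%g",
                                  width_ms, sharpness))
}

#' Default synthetic dictionary for one channel
#'
#' 8 ripple templates (90-220 Hz), 8 fast-ripple templates (260-450 Hz) and
#' 8 spikes (width 40-120 ms), with varied cycle counts, modulation depths
#' and sharpness, emulating across-structure event diversity.
#'
#' @param fs Sampling rate (Hz).
#' @param seed Seed controlling the (deterministic) parameter draws.
#' @return A list with elements `R`, `FR`, `SPK`, each a list of
#'   [event_template()]s.
#' @export
make_default_dictionary <- function(fs = 2048, seed = 1) {
  pars <- with_seed(seed, list(
    r_f0 = seq(90, 220, length.out = 8),
    r_cyc = sample(6:9, 8, replace = TRUE),
    r_am = stats::runif(8, 0, 0.4),
    r_fm = stats::runif(8, -1, 1),
    fr_f0 = seq(280, 450, length.out = 8),
    fr_cyc = sample(6:8, 8, replace = TRUE),
    fr_am = stats::runif(8, 0, 0.4),
    fr_fm = stats::runif(8, -1, 1),
    sp_w = seq(40, 120, length.out = 8),
    sp_sh = stats::runif(8, 1.0, 1.8)))
  list(
    R = lapply(1:8, function(i)
      make_synthetic_hfo(pars$r_f0[i], pars$r_cyc[i], fs, pars$r_am[i],
                         pars$r_fm[i], seed = derive_seed(seed, "R", i))),
    FR = lapply(1:8, function(i)
      make_synthetic_hfo(pars$fr_f0[i], pars$fr_cyc[i], fs, pars$fr_am[i],
                         pars$fr_fm[i], seed = derive_seed(seed, "FR", i))),
    SPK = lapply(1:8, function(i)
      make_synthetic_spike(pars$sp_w[i], pars$sp_sh[i], fs)))
}

#' Write / read a dictionary (JSON index + CSV waveforms)
#' @param dict Dictionary as returned by [make_default_dictionary()].
#' @param dir Target directory.
#' @return `read_dictionary` returns the dictionary; every template is
#'   re-validated on load.
#' @export
write_dictionary <- function(dict, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index <- list()
  for (kind in names(dict)) {
    for (i in seq_along(dict[[kind]])) {
      tpl <- dict[[kind]][[i]]
      fn <- sprintf("%s_%02d.csv", kind, i)
      utils::write.csv(data.frame(amplitude = tpl$waveform),
                       file.path(dir, fn), row.names = FALSE)
      index[[length(index) + 1]] <- list(file = fn, kind = kind,
                                         fs = tpl$fs, source = tpl$source)
    }
  }
  jsonlite::write_json(index, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"),
                               simplifyVector = FALSE)
  dict <- list(R = list(), FR = list(), SPK = list())
  for (e in index) {
    w <- utils::read.csv(file.path(dir, e$file))$amplitude
    dict[[e$kind]][[length(dict[[e$kind]]) + 1]] <-
      event_template(w, e$fs, e$kind, e$source)
  }
  dict
}
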