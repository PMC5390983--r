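# FIR band-pass front-end and band-power measurement.

# Design cache: FIR band-pass kernels keyed by (fs, lo, hi, order).
.fir_cache <- new.env(parent = emptyenv())

fir_bandpass_kernel <- function(fs, f_lo, f_hi, order = 512L) {
  key <- paste(fs, f_lo, f_hi, order, sep = "_")
  if (!is.null(.fir_cache[[key]])) return(.fir_cache[[key]])
  ny <- fs / 2
  # Blackman window for > 70 dB stopband attenuation.
  h <- signal::fir1(order, c(f_lo, f_hi) / ny, type = "pass",
                    window = signal::blackman(order + 1))
  .fir_cache[[key]] <- as.numeric(h)
  h
}

# Zero-phase FIR band-pass: pad, overlap-add filter, compensate the linear
# phase delay of order/2 samples. Output length = input length.
fir_bandpass <- function(x, fs, f_lo, f_hi, order = 512L) {
  h <- fir_bandpass_kernel(fs, f_lo, f_hi, order)
  pad <- order
  xp <- c(numeric(pad), x, numeric(pad))
  y <- signal::fftfilt(h, xp)
  d <- order / 2
  y[(pad + d + 1):(pad + d + length(x))]
}

#' Band-pass filter 80-500 Hz
#'
#' The common front-end of the time-domain detectors: zero-phase FIR
#' band-pass with 80-500 Hz passband and > 60 dB stopband attenuation.
#' Output length equals input length.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz), must exceed 1000 Hz so the 500 Hz passband
#'   edge is below Nyquist.
#' @param order FIR order (default 512).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_80_500 <- function(x, fs, order = 512L) {
  assert_numeric_signal(x)
  if (fs <= 1000)
    stop("'fs' must exceed 1000 Hz for an 80-500 Hz passband", call. = FALSE)
  fir_bandpass(x, fs, 80, 500, order)
}

#' Mean band-limited power of a waveform
#'
#' Mean squared amplitude of the band-pass-filtered waveform over its own
#' support. Short waveforms are zero-padded before filtering so the FIR
#' transient does not truncate them; power is measured over the original
#' support. This is the quantity the per-band SNR contract is written in.
#'
#' @param waveform Numeric vector.
#' @param band `c(f_lo, f_hi)` in Hz with `0 <= f_lo < f_hi <= fs/2`.
#' @param fs Sampling rate (Hz).
#' @return Scalar mean power.
#' @export
band_power <- function(waveform, band, fs) {
  if (length(waveform) == 0L) stop("empty waveform", call. = FALSE)
  assert_numeric_signal(waveform, "waveform")
  if (band[1] < 0 || band[2] <= band[1] || band[2] > fs / 2)
    stop("invalid band: need 0 <= f_lo < f_hi <= fs/2", call. = FALSE)
  f_lo <- max(band[1], 1e-6 * fs)
  # band-power measurement wants sharp edges (templates can sit near a band
  # edge); a low passband edge (broadband spike reference) needs the longest
  # kernel for a usable transition width
  order <- if (f_lo < 20) 2048L else 1024L
  y <- fir_bandpass(waveform, fs, f_lo, band[2], order)
  mean(y^2)
}

# Standard analysis bands.
band_for_kind <- function(kind, fs = 2048) {
  switch(kind,
         R = c(80, 250),
         FR = c(250, 500),
         SPK = c(1, 500),
         stop(sprintf("unknown event kind '%s'", kind), call. = FALSE))
}
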