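# Shared time-frequency machinery: log-scale analytic wavelet transform,
# robust per-frequency background normalization (Gaussian fit within Tukey's
# range), wavelet entropy of the autocorrelation, and the spectral identities
# that explain the line-length detector's frequency bias.

MORLET_OMEGA0 <- 6

# Per-row frequency responses of the analytic Morlet bank on the FFT grid of
# an n-sample signal: Gaussian of constant relative bandwidth, peak 1,
# positive frequencies only.
morlet_bank <- function(n, fs, freqs, omega0 = MORLET_OMEGA0) {
  fgrid <- (0:(n - 1)) * fs / n
  pos <- fgrid <= fs / 2
  H <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    fa <- freqs[i]
    H[i, pos] <- exp(-0.5 * omega0^2 * ((fgrid[pos] - fa) / fa)^2)
  }
  H[, 1] <- 0                     # DC removed
  H
}

#' Log-scale analytic wavelet transform
#'
#' Complex Morlet transform on log-spaced frequencies. Rows are
#' peak-normalized in frequency: a unit-amplitude tone at a grid frequency
#' yields unit coefficient magnitude in its row, so oscillations have a
#' comparable footprint at every frequency of the log axis.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param f_min,f_max Frequency range (Hz), `f_max < fs/2`.
#' @param voices_per_octave Rows per octave (default 12).
#' @return A `tf_map`: list with complex `coefficients`
#'   (frequency rows x time columns, rows ordered by increasing frequency),
#'   `freqs_hz`, `fs`, `wavelet`, and per-row squared-response integrals
#'   `h2_int` used for background-power calibration.
#' @export
cwt_logscale <- function(x, fs, f_min = 10, f_max = 512,
                         voices_per_octave = 12) {
  assert_numeric_signal(x)
  if (f_min <= 0 || f_max <= f_min || f_max >= fs / 2)
    stop("invalid frequency range: need 0 < f_min < f_max < fs/2",
         call. = FALSE)
  n <- length(x)
  n_oct <- log2(f_max / f_min)
  k <- 0:floor(n_oct * voices_per_octave)
  freqs <- f_min * 2^(k / voices_per_octave)
  X <- stats::fft(x)
  fgrid <- (0:(n - 1)) * fs / n
  npos <- sum(fgrid <= fs / 2)
  co <- matrix(0i, nrow = length(freqs), ncol = n)
  h2 <- numeric(length(freqs))
  for (i in seq_along(freqs)) {
    fa <- freqs[i]
    # Gaussian response support: |f - fa| < 9.3 sigma_f covers exp(-43)
    half <- 13 * fa / MORLET_OMEGA0
    j <- max(2L, ceiling((fa - half) * n / fs)):
      min(npos, floor((fa + half) * n / fs) + 1L)
    H <- exp(-0.5 * MORLET_OMEGA0^2 * ((fgrid[j] - fa) / fa)^2)
    Xi <- complex(length.out = n)
    Xi[j] <- X[j] * (2 * H)
    co[i, ] <- stats::fft(Xi, inverse = TRUE) / n
    h2[i] <- sum(H^2) * fs / n
  }
  structure(list(coefficients = co, freqs_hz = freqs, fs = fs,
                 wavelet = sprintf("morlet omega0=%g", MORLET_OMEGA0),
                 h2_int = h2),
            class = "tf_map")
}

# SD of a standard normal truncated to Tukey's fences (+-2.698 sigma):
# sqrt(1 - 2*a*dnorm(a)/(2*pnorm(a)-1)) with a = 2.698; used to de-bias the
# within-fence sample SD so a pure Gaussian row returns its true SD.
TUKEY_TRUNC_SD <- local({
  a <- 2.698
  sqrt(1 - 2 * a * stats::dnorm(a) / (2 * stats::pnorm(a) - 1))
})

#' Robust per-frequency normalization of a TF map
#'
#' For each frequency row, a Gaussian is fitted to the real coefficients
#' within Tukey's range (values inside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`); the
#' truncation-corrected SD estimates the background level at that frequency
#' regardless of events present in the record. Real and imaginary parts are
#' z-scored by this SD, and the normalized energy `(z_re^2 + z_im^2)/2` is
#' the detection statistic of the time-frequency detector.
#'
#' @param tf A `tf_map` from [cwt_logscale()].
#' @param keep_z If `FALSE`, omit the complex normalized map from the result
#'   (the energy map is always returned); saves a large allocation on long
#'   records.
#' @return List with `stats` (data.frame: freq_hz, mu, sigma, bkg_power,
#'   n_kept), `z` (complex normalized map, `NULL` if `keep_z = FALSE`) and
#'   `energy` (normalized energy map).
#' @export
zh0_normalize <- function(tf, keep_z = TRUE) {
  stopifnot(inherits(tf, "tf_map"))
  nt <- ncol(tf$coefficients)
  if (nt < 2 * tf$fs)
    stop("record shorter than 2 s: normalization unstable", call. = FALSE)
  nf <- nrow(tf$coefficients)
  mu <- sigma <- bkgp <- nkept <- numeric(nf)
  z <- if (keep_z) tf$coefficients else NULL
  energy <- matrix(0, nf, nt)
  qsub <- if (nt > 2^16) seq(1L, nt, by = 4L) else seq_len(nt)
  for (i in seq_len(nf)) {
    re <- Re(tf$coefficients[i, ])
    q <- stats::quantile(re[qsub], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    if (iqr <= 0)
      stop(sprintf("degenerate coefficient row at %.1f Hz (zero IQR)",
                   tf$freqs_hz[i]), call. = FALSE)
    keep <- re >= q[1] - 1.5 * iqr & re <= q[2] + 1.5 * iqr
    mu[i] <- mean(re[keep])
    sigma[i] <- stats::sd(re[keep]) / TUKEY_TRUNC_SD
    nkept[i] <- sum(keep)
    im <- Im(tf$coefficients[i, ])
    mu_im <- mean(im[keep])
    zre <- (re - mu[i]) / sigma[i]
    zim <- (im - mu_im) / sigma[i]
    if (keep_z) z[i, ] <- complex(real = zre, imaginary = zim)
    energy[i, ] <- (zre^2 + zim^2) / 2
    # row variance of a constant-Q bank scales as PSD(f) * bandwidth(f);
    # dividing by the squared-response integral recovers the PSD shape
    bkgp[i] <- sigma[i]^2 / tf$h2_int[i]
  }
  list(stats = data.frame(freq_hz = tf$freqs_hz, mu = mu, sigma = sigma,
                          bkg_power = bkgp, n_kept = nkept),
       z = z, energy = energy)
}

#' Scale set for wavelet entropy
#'
#' Four voices per octave over the 80-500 Hz band (11 scales); recorded with
#' every entropy profile so the theoretical maximum `log10(|A|)` is always
#' computable.
#' @return Numeric vector of analysis frequencies (Hz).
#' @export
we_scales <- function() 80 * 2^(seq(0, 10) / 4)

#' Wavelet entropy of a window's autocorrelation
#'
#' Biased autocorrelation of the (band-passed) window, analytic-wavelet
#' coefficients at the scale set `scales_hz` evaluated at the zero-lag
#' column, normalized to a probability across scales, and Shannon entropy in
#' base 10. Rows are L2-normalized (equal impulse-response energy), under
#' which an ideal white background scores close to the theoretical maximum
#' `log10(length(scales_hz))` while rhythmic windows concentrate power at
#' one scale and score low.
#'
#' @param window Numeric window, already band-passed to 80-500 Hz.
#' @param fs Sampling rate (Hz).
#' @param scales_hz Analysis frequencies; default [we_scales()].
#' @return List with `S` (entropy), `P` (normalized powers), `scales_hz`,
#'   `S_max` (theoretical maximum).
#' @export
wavelet_entropy <- function(window, fs, scales_hz = we_scales()) {
  assert_numeric_signal(window, "window")
  if (all(window == 0)) stop("all-zero window", call. = FALSE)
  n <- length(window)
  # biased autocorrelation via FFT, centered (lags -(n-1) .. n-1)
  nfft <- 2^ceiling(log2(2 * n))
  r <- Re(stats::fft(Mod(stats::fft(c(window, numeric(nfft - n))))^2,
                     inverse = TRUE)) / nfft / n
  acf2 <- c(r[(nfft - n + 2):nfft], r[1:n])      # centered, length 2n-1
  m <- length(acf2)
  H <- morlet_bank(m, fs, scales_hz)
  l2 <- sqrt(rowSums(H^2))
  A <- stats::fft(acf2)
  center <- n                                     # zero-lag column
  Tz <- vapply(seq_along(scales_hz), function(i) {
    row <- stats::fft(A * (2 * H[i, ] / l2[i]), inverse = TRUE) / m
    row[center]
  }, complex(1))
  P <- Mod(Tz)^2
  P <- P / sum(P)
  S <- -sum(ifelse(P > 0, P * log10(P), 0))
  list(S = S, P = P, scales_hz = scales_hz, S_max = log10(length(scales_hz)))
}

#' Squared-magnitude response of second-order differencing
#'
#' Returns `2 (3 + cos 2w - 4 cos w)`, the closed trigonometric form of
#' `|1 - exp(-jw)|^4`, the PSD factor a twice-differencing stage applies at
#' normalized frequency `w` (rad/sample). It vanishes at DC and grows
#' monotonically to 16 at Nyquist, which is why a line-length stage on a
#' differenced signal over-expresses fast ripples relative to ripples.
#'
#' @param omega Normalized frequency in `[0, pi]`.
#' @return Numeric factor(s).
#' @export
second_diff_psd_factor <- function(omega) {
  if (any(omega < 0 | omega > pi))
    stop("'omega' must lie in [0, pi]", call. = FALSE)
  2 * (3 + cos(2 * omega) - 4 * cos(omega))
}

#' Line-length / second-difference identity
#'
#' Computes, by two independent code paths, (a) the sliding line length of
#' the first-differenced signal and (b) the sliding sum of the absolute
#' second difference, and returns their maximum absolute discrepancy
#' (analytically zero).
#'
#' @param x Numeric signal, `length(x) > W + 2`.
#' @param W Window length in samples.
#' @return Scalar maximum absolute discrepancy.
#' @export
sll_second_diff_equivalence <- function(x, W = 25L) {
  assert_numeric_signal(x)
  if (length(x) <= W + 2) stop("signal too short for window", call. = FALSE)
  x1 <- x[-1] - x[-length(x)]                    # first backward difference
  ll <- abs(x1[-1] - x1[-length(x1)])            # line length elements
  e1 <- stats::filter(ll, rep(1, W - 1), sides = 1)
  n <- length(x)
  x2 <- x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)] # direct second difference
  e2 <- stats::filter(abs(x2), rep(1, W - 1), sides = 1)
  max(abs(e1 - e2), na.rm = TRUE)
}

#' Welch power spectral density
#'
#' Hann-windowed averaged periodogram with 50% overlap; the package's
#' spectrum oracle for AR synthesis and whitening diagnostics.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param nfft Segment length (default 4096).
#' @return data.frame with `freq_hz` and `power` (one-sided density shape).
#' @export
welch_psd <- function(x, fs, nfft = 4096L) {
  assert_numeric_signal(x)
  n <- length(x)
  if (n < nfft) nfft <- 2^floor(log2(n))
  step <- nfft %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / nfft)
  starts <- seq(1, n - nfft + 1, by = step)
  acc <- numeric(nfft %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + nfft - 1)] * win
    P <- Mod(stats::fft(seg))^2
    acc <- acc + P[1:(nfft %/% 2 + 1)]
  }
  acc <- acc / length(starts) / sum(win^2)
  data.frame(freq_hz = (0:(nfft %/% 2)) * fs / nfft, power = acc)
}

#' Log-log PSD slope
#'
#' Least-squares slope of `log10(power)` against `log10(frequency)` over a
#' frequency range, used to compare raw, once- and twice-differenced
#' background spectra.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param frange Frequency range for the fit (Hz).
#' @return Scalar slope (decades of power per decade of frequency).
#' @export
psd_loglog_slope <- function(x, fs, frange = c(10, 500)) {
  p <- welch_psd(x, fs)
  sel <- p$freq_hz >= frange[1] & p$freq_hz <= frange[2] & p$power > 0
  stats::coef(stats::lm(log10(power) ~ log10(freq_hz), data = p[sel, ]))[[2]]
}
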