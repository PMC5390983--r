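# Autoregressive background models: estimation from baseline segments,
# per-channel averaging, synthesis of statistically identical realizations.

#' Baseline segment container
#'
#' A marked stretch of background-only recording from one channel, used to
#' fit the channel's autoregressive (AR) background model.
#'
#' @param samples Numeric vector, bipolar-montage amplitude (arbitrary units).
#' @param fs Sampling rate in Hz.
#' @param channel_id Channel label.
#' @return An object of class `baseline_segment`.
#' @export
baseline_segment <- function(samples, fs, channel_id = "chan") {
  assert_numeric_signal(samples, "samples")
  if (!is.numeric(fs) || fs <= 0) stop("'fs' must be positive", call. = FALSE)
  if (length(samples) < 2 * fs)
    stop(sprintf("baseline segment for '%s' shorter than 2 s (%d samples at %g Hz)",
                 channel_id, length(samples), fs), call. = FALSE)
  structure(list(channel_id = channel_id, samples = as.numeric(samples),
                 fs = fs), class = "baseline_segment")
}

new_ar_model <- function(channel_id, coeffs, gain, fs) {
  m <- structure(list(channel_id = channel_id, order = length(coeffs),
                      coeffs = as.numeric(coeffs), gain = gain, fs = fs),
                 class = "ar_background_model")
  m
}

#' AR model poles
#'
#' Roots of the synthesis filter denominator `z^p + a1 z^(p-1) + ... + ap`;
#' the model is stable iff all moduli are < 1.
#' @param model An `ar_background_model`.
#' @return Complex vector of poles (possibly empty for order 0).
#' @export
ar_poles <- function(model) {
  p <- model$order
  if (p == 0L) return(complex(0))
  polyroot(rev(c(1, model$coeffs)))
}

#' @export
print.ar_background_model <- function(x, ...) {
  cat(sprintf("AR background model '%s': order %d, gain %.4g, fs %g Hz\n",
              x$channel_id, x$order, x$gain, x$fs))
  if (x$order > 0)
    cat(sprintf("  max pole modulus: %.4f\n", max(Mod(ar_poles(x)))))
  invisible(x)
}

ar_is_stable <- function(model) {
  model$order == 0L || max(Mod(ar_poles(model))) < 1
}

# |A(e^{j w})|^2 evaluated on a uniform grid of nfft points over [0, 2*pi),
# with A(z) = 1 + sum a_i z^-i (prediction-filter convention).
ar_abs_A2_grid <- function(coeffs, nfft = 4096L) {
  a <- c(1, coeffs)
  Mod(stats::fft(c(a, numeric(nfft - length(a)))))^2
}

#' Fit an AR background model to a baseline segment
#'
#' Autocorrelation (Levinson-Durbin / Yule-Walker) fit, the same family as
#' classical LPC routines. The segment mean is removed before fitting and the
#' innovation gain is set so that the model PSD integrates to the segment's
#' variance.
#'
#' @param segment A [baseline_segment()].
#' @param order AR order `p >= 1`. At 2048 Hz an order around 30 captures the
#'   spectral slope plus rhythmic peaks up to ~500 Hz.
#' @return An `ar_background_model` with fields `channel_id`, `order`,
#'   `coeffs` (prediction-filter convention, implicit leading 1), `gain`
#'   (innovation SD) and `fs`.
#' @export
estimate_ar <- function(segment, order = 30L) {
  stopifnot(inherits(segment, "baseline_segment"))
  order <- as.integer(order)
  if (order < 1L) stop("'order' must be >= 1", call. = FALSE)
  x <- segment$samples
  if (length(x) <= 10L * order)
    stop(sprintf("segment '%s' too short (%d samples) for AR order %d (need > %d)",
                 segment$channel_id, length(x), order, 10L * order),
         call. = FALSE)
  x <- x - mean(x)
  v <- stats::var(x)
  if (v == 0)
    stop(sprintf("segment '%s' has zero variance; cannot fit an AR model",
                 segment$channel_id), call. = FALSE)
  fit <- tryCatch(
    stats::ar.yw(x, aic = FALSE, order.max = order, demean = FALSE),
    error = function(e) stop(sprintf(
      "AR fit failed for segment '%s': %s", segment$channel_id,
      conditionMessage(e)), call. = FALSE))
  coeffs <- -fit$ar                       # a_i = -phi_i
  if (anyNA(coeffs))
    stop(sprintf("numerically singular autocorrelation in segment '%s'",
                 segment$channel_id), call. = FALSE)
  # gain so that integral of PSD over frequency = var(x):
  # process variance per unit innovation variance = mean(1/|A|^2).
  vfac <- mean(1 / ar_abs_A2_grid(coeffs))
  new_ar_model(segment$channel_id, coeffs, sqrt(v / vfac), segment$fs)
}

#' Average AR models of one channel
#'
#' Element-wise mean of the coefficient vectors and gains across baseline
#' sections of the same channel. Averaging AR coefficients is not
#' stability-preserving; if the mean model is unstable, offending poles are
#' radially shrunk to modulus 0.98 (with a warning).
#'
#' @param models List of `ar_background_model`s sharing channel, order, fs.
#' @return A single `ar_background_model`.
#' @export
average_ar <- function(models) {
  if (length(models) == 0L) stop("empty model list", call. = FALSE)
  stopifnot(all(vapply(models, inherits, TRUE, "ar_background_model")))
  ords <- vapply(models, function(m) m$order, 1L)
  fss <- vapply(models, function(m) m$fs, 1)
  ids <- vapply(models, function(m) m$channel_id, "")
  if (length(unique(ords)) > 1L || length(unique(fss)) > 1L)
    stop("models have mixed orders or sampling rates", call. = FALSE)
  if (length(unique(ids)) > 1L)
    stop("models belong to different channels", call. = FALSE)
  coeffs <- rowMeans(vapply(models, function(m) m$coeffs,
                            numeric(ords[1])))
  gain <- mean(vapply(models, function(m) m$gain, 1))
  out <- new_ar_model(ids[1], coeffs, gain, fss[1])
  if (!ar_is_stable(out)) {
    warning(sprintf("averaged AR model for '%s' unstable; shrinking poles to modulus 0.98",
                    ids[1]))
    poles <- ar_poles(out)
    bad <- Mod(poles) >= 1
    poles[bad] <- poles[bad] / Mod(poles[bad]) * 0.98
    # recompose monic polynomial from poles
    pcoef <- 1
    for (r in poles) pcoef <- c(pcoef, 0) - c(0, pcoef * r)
    out$coeffs <- Re(pcoef[-1])
  }
  out
}

#' Synthesize a background realization
#'
#' Filters a fresh realization of Gaussian white noise through the AR
#' synthesis filter. A burn-in of `10 * order` samples is generated and
#' discarded so the output is stationary; the output is zero-mean by
#' construction. Identical `(model, seed)` give identical output.
#'
#' @param model Stable `ar_background_model`.
#' @param duration_s Duration in seconds (> 0).
#' @param seed Integer seed for the white-noise realization.
#' @return Numeric vector of length `round(duration_s * fs)`.
#' @export
synthesize_background <- function(model, duration_s, seed) {
  stopifnot(inherits(model, "ar_background_model"))
  if (duration_s <= 0) stop("'duration_s' must be > 0", call. = FALSE)
  if (!ar_is_stable(model))
    stop(sprintf("AR model '%s' is unstable", model$channel_id), call. = FALSE)
  n <- round(duration_s * model$fs)
  burn <- 10L * model$order
  e <- with_seed(seed, stats::rnorm(n + burn, sd = model$gain))
  if (model$order == 0L) return(e[(burn + 1):(burn + n)])
  x <- stats::filter(e, filter = -model$coeffs, method = "recursive")
  as.numeric(x[(burn + 1):(burn + n)])
}

#' Theoretical AR power spectral density
#'
#' `gain^2 / |A(e^{j 2 pi f / fs})|^2` at the requested frequencies
#' (power per radian-normalized frequency; only the shape and relative level
#' matter for the package's diagnostics).
#'
#' @param model An `ar_background_model`.
#' @param freqs Frequencies in Hz, `0 <= f < fs/2`.
#' @return Numeric vector of power values.
#' @export
ar_psd <- function(model, freqs) {
  stopifnot(inherits(model, "ar_background_model"))
  if (any(freqs < 0 | freqs >= model$fs / 2))
    stop("frequencies must satisfy 0 <= f < fs/2", call. = FALSE)
  w <- 2 * pi * freqs / model$fs
  a <- c(1, model$coeffs)
  A <- vapply(w, function(wi) sum(a * exp(-1i * wi * (seq_along(a) - 1))),
              complex(1))
  model$gain^2 / Mod(A)^2
}

#' Build an AR model directly from poles
#'
#' Convenience constructor for fully synthetic channels: place complex pole
#' pairs (frequency in Hz, modulus) plus optional real poles, and scale the
#' innovation gain so the process standard deviation equals `sd`.
#'
#' @param pole_freqs_hz Frequencies of complex pole pairs (Hz).
#' @param pole_moduli Moduli of those pairs (< 1).
#' @param real_poles Optional real poles (moduli < 1), e.g. 0.98 for a
#'   low-frequency 1/f-like slope.
#' @param sd Target process standard deviation.
#' @param fs Sampling rate (Hz).
#' @param channel_id Label.
#' @return An `ar_background_model`.
#' @export
ar_model_from_poles <- function(pole_freqs_hz, pole_moduli, real_poles = numeric(0),
                                sd = 1, fs = 2048, channel_id = "synth") {
  stopifnot(length(pole_freqs_hz) == length(pole_moduli))
  if (any(pole_moduli >= 1) || any(abs(real_poles) >= 1))
    stop("pole moduli must be < 1", call. = FALSE)
  poles <- complex(0)
  for (i in seq_along(pole_freqs_hz)) {
    th <- 2 * pi * pole_freqs_hz[i] / fs
    p <- pole_moduli[i] * exp(1i * th)
    poles <- c(poles, p, Conj(p))
  }
  poles <- c(poles, as.complex(real_poles))
  pcoef <- 1
  for (r in poles) pcoef <- c(pcoef, 0) - c(0, pcoef * r)
  coeffs <- Re(pcoef[-1])
  vfac <- mean(1 / ar_abs_A2_grid(coeffs))
  new_ar_model(channel_id, coeffs, sd / sqrt(vfac), fs)
}

#' Serialize / deserialize AR models as JSON
#' @param model An `ar_background_model`.
#' @param path File path.
#' @return `read_ar_model` returns an `ar_background_model`.
#' @export
write_ar_model <- function(model, path) {
  stopifnot(inherits(model, "ar_background_model"))
  jsonlite::write_json(
    list(channel_id = model$channel_id, order = model$order,
         coeffs = model$coeffs, gain = model$gain, fs = model$fs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ar_model
#' @export
read_ar_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_ar_model(j$channel_id, j$coeffs, j$gain, j$fs)
}
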