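# Internal helpers shared across modules.

#' @keywords internal
assert_numeric_signal <- function(x, name = "signal") {
  if (!is.numeric(x) || length(x) == 0L)
    stop(sprintf("'%s' must be a non-empty numeric vector", name), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains NA/Inf values", name), call. = FALSE)
  invisible(x)
}

#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams (background, timeline, event draws, ...). Deterministic;
#' results stay below 2^31 - 1 (R integer range).
#'
#' @param seed Master seed (integer).
#' @param ... Stream tags (strings or integers).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  tags <- unlist(list(...), use.names = FALSE)
  h <- as.double(seed %% 2147483647)
  for (tag in tags) {
    if (is.character(tag)) {
      bytes <- utf8ToInt(tag)
    } else {
      bytes <- as.integer(tag)
    }
    for (b in bytes) h <- (h * 69069 + as.double(b) + 1) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Analytic signal via the FFT construction (positive frequencies doubled).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Tukey (tapered cosine) window, taper fraction `alpha` split across both ends.
tukey_window <- function(n, alpha = 0.25) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / alpha + 1)))
  w
}

# Centered moving average with edge shrinkage (partial windows at the ends).
moving_mean <- function(x, w) {
  w <- max(1L, as.integer(w))
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  i0 <- pmax(0L, seq_len(n) - 1L - half)
  i1 <- pmin(n, seq_len(n) - 1L + (w - half))
  (cs[i1 + 1L] - cs[i0 + 1L]) / (i1 - i0)
}

# Runs of TRUE in a logical vector -> matrix of (start, end) indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Merge index runs whose gaps are < gap samples.
merge_runs <- function(runs, gap) {
  if (nrow(runs) <= 1L) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs[i, "start"] - out[nrow(out), "end"] - 1L < gap) {
      out[nrow(out), "end"] <- runs[i, "end"]
    } else {
      out <- rbind(out, runs[i, , drop = FALSE])
    }
  }
  out
}

empty_detections <- function(detector = character(0)) {
  data.frame(detector = character(0), t_start_s = numeric(0),
             t_end_s = numeric(0), t_peak_s = numeric(0),
             type = character(0), peak_freq_hz = numeric(0),
             score = numeric(0), stringsAsFactors = FALSE)
}
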