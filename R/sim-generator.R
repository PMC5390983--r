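# Benchmark channel assembly: Poisson event timelines over 7 classes,
# per-band SNR scaling, spike stretch + post-spike silencing, HFO jitter,
# and ground-truth bookkeeping.

CLASS_COMPONENTS <- list(
  `1` = "SPK", `2` = c("SPK", "R"), `3` = c("SPK", "FR"),
  `4` = c("SPK", "R", "FR"), `5` = "R", `6` = "FR", `7` = c("R", "FR"))

CLASS_LABELS <- c("Spk", "Spk-R", "Spk-FR", "Spk-R-FR", "R", "FR", "R-FR")

#' Simulation configuration
#'
#' Defaults are the benchmark profile: 3 events/min for each of the seven
#' classes, HFO SNR fixed per realization on the 0/5/10/15 dB grid, spike
#' SNR uniform in 0-15 dB, stretch factor uniform in (0.8, 1.25), HFO
#' timing jitter +-20 ms when riding another event, post-spike silencing
#' depth 0.5.
#'
#' @param class_rates Events/min for classes 1 Spk, 2 Spk-R, 3 Spk-FR,
#'   4 Spk-R-FR, 5 R, 6 FR, 7 R-FR.
#' @param hfo_snr_db Per-band HFO SNR (dB), fixed within a realization.
#' @param spk_snr_range_db Range for the per-spike uniform SNR draw (dB).
#' @param duration_s Record duration (s).
#' @param n_realizations Realizations per channel and SNR.
#' @param snr_grid_db SNR grid for benchmark generation.
#' @param stretch_range Spike time-stretch factor range `(k_lo, k_hi)`.
#' @param jitter_ms Maximal absolute HFO timing jitter (ms).
#' @param silencing_depth Post-spike background amplitude dip, 0-1.
#' @param fs Sampling rate (Hz).
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(class_rates = rep(3, 7), hfo_snr_db = 10,
                       spk_snr_range_db = c(0, 15), duration_s = 120,
                       n_realizations = 1, snr_grid_db = c(0, 5, 10, 15),
                       stretch_range = c(0.8, 1.25), jitter_ms = 20,
                       silencing_depth = 0.5, fs = 2048, seed = 1) {
  stopifnot(length(class_rates) == 7, all(class_rates >= 0),
            all(is.finite(snr_grid_db)), stretch_range[1] > 0,
            silencing_depth >= 0, silencing_depth <= 1)
  structure(list(class_rates = class_rates, hfo_snr_db = hfo_snr_db,
                 spk_snr_range_db = spk_snr_range_db,
                 duration_s = duration_s, n_realizations = n_realizations,
                 snr_grid_db = snr_grid_db, stretch_range = stretch_range,
                 jitter_ms = jitter_ms, silencing_depth = silencing_depth,
                 fs = fs, seed = seed), class = "sim_config")
}

EDGE_GUARD_S <- 1           # no event centers within 1 s of the record edges
MIN_SPACING_S <- 0.5        # minimum inter-event spacing (keeps CIs disjoint)

#' Draw an event timeline
#'
#' Homogeneous Poisson arrivals at the summed class rate; each arrival's
#' class is drawn with probability proportional to its rate. Arrivals closer
#' than 500 ms to an accepted event, or within the 1 s edge guard, are
#' re-drawn.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return data.frame with `t_s` (sorted) and `class_id`.
#' @export
draw_event_timeline <- function(config, seed) {
  rates <- config$class_rates
  total <- sum(rates) / 60                 # events per second
  if (total <= 0) stop("total event rate must be > 0", call. = FALSE)
  dur <- config$duration_s
  if (dur <= 2 * EDGE_GUARD_S + MIN_SPACING_S)
    stop("duration too short to host one event", call. = FALSE)
  with_seed(seed, {
    n <- stats::rpois(1, total * dur)
    t <- numeric(0)
    for (i in seq_len(n)) {
      for (try in 1:200) {
        cand <- stats::runif(1, EDGE_GUARD_S, dur - EDGE_GUARD_S)
        if (!length(t) || min(abs(t - cand)) >= MIN_SPACING_S) {
          t <- c(t, cand); break
        }
      }
    }
    cls <- sample.int(7, length(t), replace = TRUE, prob = rates)
    o <- order(t)
    data.frame(t_s = t[o], class_id = cls[o])
  })
}

#' Scale a template to a target per-band SNR
#'
#' Returns `g * waveform` with the gain `g` solving
#' `10 log10(band_power(g w) / band_power(bkg in template band)) = snr_db`;
#' event and background band powers are measured with the same band-pass
#' filter. At 0 dB the event's in-band power equals the background's.
#'
#' @param template An [event_template()].
#' @param bkg Background signal (>= 5 s for a stable band-power estimate).
#' @param snr_db Target SNR (dB).
#' @return Scaled waveform (numeric vector), with the gain as attribute
#'   `"gain"`.
#' @export
scale_to_snr <- function(template, bkg, snr_db) {
  stopifnot(inherits(template, "event_template"))
  if (length(bkg) < 5 * template$fs)
    stop("background shorter than 5 s: band-power estimate unstable",
         call. = FALSE)
  p_t <- band_power(template$waveform, template$band, template$fs)
  if (p_t <= 0) stop("zero-energy template", call. = FALSE)
  p_b <- band_power(bkg, template$band, template$fs)
  g <- sqrt(10^(snr_db / 10) * p_b / p_t)
  structure(template$waveform * g, gain = g)
}

# Resample a waveform in time by factor k (duration multiplied by k),
# cubic-spline interpolation on the original support.
stretch_waveform <- function(w, k) {
  n <- length(w)
  n2 <- max(4L, round(n * k))
  stats::spline(x = seq_len(n), y = w,
                xout = seq(1, n, length.out = n2))$y
}

#' Insert a spike with post-spike silencing
#'
#' The spike is stretched in time by `k`, scaled to a broadband (1-500 Hz)
#' SNR against the background, and added at `t_s`; simultaneously the
#' background is multiplied by a raised-cosine notch dipping to
#' `1 - silencing_depth` over the spike support, reproducing post-spike
#' suppression of ongoing activity.
#'
#' @param bkg Background signal.
#' @param spike A `"SPK"` [event_template()].
#' @param t_s Spike centre time (s).
#' @param k Stretch factor.
#' @param snr_db Broadband SNR (dB).
#' @param silencing_depth Notch depth, 0-1.
#' @param bkg_band_power Optional precomputed broadband background power.
#' @return Modified signal; attributes `"support"` (sample index range) and
#'   `"gain"`.
#' @export
insert_spike <- function(bkg, spike, t_s, k = 1, snr_db = 5,
                         silencing_depth = 0.5, bkg_band_power = NULL) {
  stopifnot(inherits(spike, "event_template"), spike$kind == "SPK")
  fs <- spike$fs
  w <- stretch_waveform(spike$waveform, k)
  n <- length(w)
  i0 <- round(t_s * fs) - n %/% 2 + 1L
  i1 <- i0 + n - 1L
  if (i0 < 1L || i1 > length(bkg))
    stop("spike support falls outside the record", call. = FALSE)
  p_b <- if (is.null(bkg_band_power)) band_power(bkg, c(1, 500), fs) else
    bkg_band_power
  p_s <- band_power(w, c(1, 500), fs)
  g <- sqrt(10^(snr_db / 10) * p_b / p_s)
  out <- bkg
  if (silencing_depth > 0) {
    notch <- 1 - silencing_depth *
      (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
    out[i0:i1] <- out[i0:i1] * notch
  }
  out[i0:i1] <- out[i0:i1] + g * w
  structure(out, support = c(i0, i1), gain = g)
}

# Add a scaled HFO waveform centred at t_s.
add_waveform <- function(x, w, t_s, fs) {
  n <- length(w)
  i0 <- round(t_s * fs) - n %/% 2 + 1L
  i1 <- i0 + n - 1L
  if (i0 < 1L || i1 > length(x))
    stop("event support falls outside the record", call. = FALSE)
  x[i0:i1] <- x[i0:i1] + w
  x
}

#' Generate one simulated channel
#'
#' Draws a fresh background realization and an event timeline, scales every
#' HFO component to the fixed per-band SNR (measured against the event-free
#' background of this very realization), every spike to a uniform random
#' broadband SNR, applies spike stretching and post-spike silencing, jitters
#' HFOs that co-occur with a spike or another HFO, and records complete
#' ground truth.
#'
#' @param model `ar_background_model` of the channel.
#' @param dictionary Dictionary (`list(R=, FR=, SPK=)` of templates).
#' @param config A [sim_config()].
#' @param snr_db HFO SNR for this realization (dB).
#' @param realization_seed Integer seed; identical seeds give bit-identical
#'   output.
#' @return A `simulated_channel`: list with `samples`, `fs`, `ground_truth`
#'   (data.frame: event_id, class_id, kind, t_center_s, snr_db, k, jitter_s),
#'   `model_id`, `snr_db`, `seed`.
#' @export
generate_channel <- function(model, dictionary, config, snr_db,
                             realization_seed) {
  fs <- model$fs
  bkg <- synthesize_background(model, config$duration_s,
                               seed = derive_seed(realization_seed, "bkg"))
  timeline <- if (sum(config$class_rates) > 0)
    draw_event_timeline(config, seed = derive_seed(realization_seed, "timeline"))
  else
    data.frame(t_s = numeric(0), class_id = integer(0))
  if (!nrow(timeline))
    return(structure(list(samples = bkg, fs = fs,
                          ground_truth = data.frame(
                            event_id = integer(0), class_id = integer(0),
                            kind = character(0), t_center_s = numeric(0),
                            snr_db = numeric(0), k = numeric(0),
                            jitter_s = numeric(0)),
                          model_id = model$channel_id, snr_db = snr_db,
                          config = config, seed = realization_seed),
                     class = "simulated_channel"))
  needed <- unique(unlist(CLASS_COMPONENTS[as.character(timeline$class_id)]))
  for (kind in needed)
    if (!length(dictionary[[kind]]))
      stop(sprintf("dictionary has no '%s' template", kind), call. = FALSE)

  # band powers of the clean background, one per band
  p_spk <- band_power(bkg, c(1, 500), fs)
  p_band <- list(R = band_power(bkg, c(80, 250), fs),
                 FR = band_power(bkg, c(250, 500), fs))

  x <- bkg
  gt <- list()
  hfo_queue <- list()
  with_seed(derive_seed(realization_seed, "events"), {
    for (ev in seq_len(nrow(timeline))) {
      t0 <- timeline$t_s[ev]
      cid <- timeline$class_id[ev]
      comps <- CLASS_COMPONENTS[[as.character(cid)]]
      multi <- length(comps) > 1L
      for (kind in comps) {
        tpl <- dictionary[[kind]][[sample.int(length(dictionary[[kind]]), 1)]]
        if (kind == "SPK") {
          k <- stats::runif(1, config$stretch_range[1], config$stretch_range[2])
          s_snr <- stats::runif(1, config$spk_snr_range_db[1],
                                config$spk_snr_range_db[2])
          x <- insert_spike(x, tpl, t0, k, s_snr, config$silencing_depth,
                            bkg_band_power = p_spk)
          gt[[length(gt) + 1]] <- data.frame(
            event_id = ev, class_id = cid, kind = "SPK", t_center_s = t0,
            snr_db = s_snr, k = k, jitter_s = 0)
        } else {
          jit <- if (multi)
            stats::runif(1, -config$jitter_ms, config$jitter_ms) / 1000
          else 0
          w <- template_scaled_band(tpl, p_band[[kind]], snr_db)
          hfo_queue[[length(hfo_queue) + 1]] <-
            list(w = w, t = t0 + jit)
          gt[[length(gt) + 1]] <- data.frame(
            event_id = ev, class_id = cid, kind = kind, t_center_s = t0 + jit,
            snr_db = snr_db, k = 1, jitter_s = jit)
        }
      }
    }
  })
  # HFOs added after all spikes so silencing never attenuates them
  for (q in hfo_queue) x <- add_waveform(x, q$w, q$t, fs)
  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(event_id = integer(0), class_id = integer(0),
               kind = character(0), t_center_s = numeric(0),
               snr_db = numeric(0), k = numeric(0), jitter_s = numeric(0))
  structure(list(samples = x, fs = fs, ground_truth = gt,
                 model_id = model$channel_id, snr_db = snr_db,
                 config = config, seed = realization_seed),
            class = "simulated_channel")
}

# scale template to target band SNR given a precomputed background band power
template_scaled_band <- function(tpl, p_b, snr_db) {
  p_t <- band_power(tpl$waveform, tpl$band, tpl$fs)
  if (p_t <= 0) stop("zero-energy template", call. = FALSE)
  tpl$waveform * sqrt(10^(snr_db / 10) * p_b / p_t)
}

#' Generate a benchmark dataset on disk
#'
#' Directory tree `channel/snrXX/realNN` with an EDF signal, a ground-truth
#' TSV and a JSON sidecar per record, plus a manifest; fully deterministic
#' given the master seed in `config`.
#'
#' @param models List of `ar_background_model`s.
#' @param dictionaries Either one dictionary shared by all channels or a
#'   named list of per-channel dictionaries.
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @return The manifest (invisibly), also written as `manifest.json`.
#' @export
generate_benchmark <- function(models, dictionaries, config, out_dir) {
  if (!length(models)) stop("need at least one channel model", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_channel <- !is.null(names(dictionaries)) &&
    all(vapply(models, function(m) m$channel_id, "") %in% names(dictionaries))
  files <- list()
  for (m in models) {
    dict <- if (per_channel) dictionaries[[m$channel_id]] else dictionaries
    for (snr in config$snr_grid_db) {
      for (r in seq_len(config$n_realizations)) {
        # realization seed shared across SNRs: the same background, timeline
        # and spike draws are re-used at every SNR, so only the HFO
        # amplitudes differ (realizations are statistically identical and
        # any threshold shift is attributable to the events alone)
        seed_r <- derive_seed(config$seed, m$channel_id, "real", r)
        chan <- generate_channel(m, dict, config, snr, seed_r)
        rel <- file.path(m$channel_id, sprintf("snr%02d", round(snr)),
                         sprintf("real%02d", r))
        dir.create(file.path(out_dir, rel), showWarnings = FALSE,
                   recursive = TRUE)
        base <- file.path(out_dir, rel, "record")
        ok <- tryCatch({
          export_channel(chan, base); TRUE
        }, error = function(e) {
          unlink(file.path(out_dir, rel), recursive = TRUE)
          stop(sprintf("failed writing '%s': %s", base, conditionMessage(e)),
               call. = FALSE)
        })
        files[[length(files) + 1]] <- list(
          channel = m$channel_id, snr_db = snr, realization = r,
          edf = paste0(file.path(rel, "record"), ".edf"),
          truth = paste0(file.path(rel, "record"), "_events.tsv"))
      }
    }
  }
  manifest <- list(channels = vapply(models, function(m) m$channel_id, ""),
                   snr_grid_db = config$snr_grid_db,
                   n_realizations = config$n_realizations,
                   duration_s = config$duration_s, fs = config$fs,
                   master_seed = config$seed, files = files,
                   format_version = "1")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
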