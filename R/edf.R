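# Minimal EDF (16-bit European Data Format) writer/reader, sufficient for
# single-channel simulated records and for reading baseline segments marked
# in a TSV file. Header dates are fixed so output bytes are deterministic.

pad_field <- function(s, width) {
  s <- substr(s, 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write a signal to an EDF file
#'
#' 16-bit EDF with one data record per second; the physical range is
#' auto-scaled with at least 2x headroom over the maximum absolute
#' amplitude, so the quantization error is below 1e-3 relative. Signals are
#' zero-padded to a whole number of seconds.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz, integer).
#' @param path Output path.
#' @param channel_label Signal label.
#' @param physical_dim Unit string (default "uV").
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, fs, path, channel_label = "sim", physical_dim = "uV") {
  assert_numeric_signal(x)
  fs <- as.integer(fs)
  n_rec <- ceiling(length(x) / fs)
  x <- c(x, numeric(n_rec * fs - length(x)))
  phys_max <- max(2 * max(abs(x)), 1e-6)
  dig <- as.integer(round(x / phys_max * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate 01-JAN-2000 X X hfobench", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(as.character(256 + 256), 8), pad_field("", 44),
    pad_field(as.character(n_rec), 8), pad_field("1", 8),
    pad_field("1", 4),
    pad_field(channel_label, 16), pad_field("simulated SEEG", 80),
    pad_field(physical_dim, 8),
    pad_field(sprintf("%.6g", -phys_max), 8),
    pad_field(sprintf("%.6g", phys_max), 8),
    pad_field("-32767", 8), pad_field("32767", 8),
    pad_field("", 80), pad_field(as.character(fs), 8), pad_field("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports multi-signal 16-bit EDF; returns all channels.
#'
#' @param path EDF file path.
#' @return List with `signals` (named list of numeric vectors), `fs`
#'   (samples per second per signal), `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  dims <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  signals <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
      signals[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin[i] + (d - dmin[i]) * scale
    }
  }
  names(signals) <- labels
  list(signals = signals, fs = spr / rec_dur, labels = labels)
}

#' Export a simulated channel (EDF + ground-truth TSV + JSON sidecar)
#'
#' @param chan A `simulated_channel` from [generate_channel()].
#' @param base Output path base; writes `<base>.edf`, `<base>_events.tsv`
#'   and `<base>.json`.
#' @return `base`, invisibly.
#' @export
export_channel <- function(chan, base) {
  stopifnot(inherits(chan, "simulated_channel"))
  write_edf(chan$samples, chan$fs, paste0(base, ".edf"),
            channel_label = chan$model_id)
  utils::write.table(chan$ground_truth, paste0(base, "_events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cfg <- chan$config
  jsonlite::write_json(
    list(model_id = chan$model_id, snr_db = chan$snr_db, fs = chan$fs,
         duration_s = length(chan$samples) / chan$fs, seed = chan$seed,
         class_rates = cfg$class_rates, jitter_ms = cfg$jitter_ms,
         stretch_range = cfg$stretch_range,
         silencing_depth = cfg$silencing_depth,
         spk_snr_range_db = cfg$spk_snr_range_db),
    paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Read baseline segments marked in a TSV file
#'
#' The marker TSV has columns `channel_id`, `t_start_s`, `t_end_s`, `label`;
#' rows labelled `"baseline"` are cut from the EDF channel of the same name.
#'
#' @param edf_path EDF file.
#' @param marker_tsv Marker TSV path.
#' @return List of [baseline_segment()]s.
#' @export
read_baseline_segments <- function(edf_path, marker_tsv) {
  edf <- read_edf(edf_path)
  mk <- utils::read.table(marker_tsv, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  mk <- mk[mk$label == "baseline", , drop = FALSE]
  lapply(seq_len(nrow(mk)), function(i) {
    ch <- mk$channel_id[i]
    if (!ch %in% edf$labels)
      stop(sprintf("channel '%s' not in EDF", ch), call. = FALSE)
    fs <- edf$fs[match(ch, edf$labels)]
    i0 <- round(mk$t_start_s[i] * fs) + 1
    i1 <- round(mk$t_end_s[i] * fs)
    baseline_segment(edf$signals[[ch]][i0:i1], fs, ch)
  })
}
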