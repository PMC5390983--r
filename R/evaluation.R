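# Scoring detections against inserted ground truth: 100 ms confidence
# intervals around every HFO component, sensitivity / precision / F-measure,
# per-class sensitivity.

#' Match detections to ground-truth confidence intervals
#'
#' A 100 ms confidence interval (CI) is centred on every inserted HFO
#' component (R/FR; spikes get none). A detection matches a CI if its
#' interval overlaps it; every detection is assigned to at most one CI (the
#' nearest centre when it overlaps several). CIs with at least one match are
#' true positives, CIs without are false negatives, and detections assigned
#' to no CI are false positives. Surplus detections inside an already
#' matched CI are neither TP nor FP.
#'
#' @param ground_truth Ground-truth data.frame (columns `kind`,
#'   `t_center_s`, `class_id`, ...) as produced by [generate_channel()].
#' @param detections Detection data.frame (columns `t_start_s`, `t_end_s`).
#' @param ci_ms CI width in milliseconds (default 100).
#' @return A `match_result`: list with counts `TP`, `FP`, `FN`, and
#'   `ci_table` (per-CI class, centre, matched flag), `assignment`
#'   (detection index -> CI index or NA).
#' @export
match_detections <- function(ground_truth, detections, ci_ms = 100) {
  hfo <- ground_truth[ground_truth$kind %in% c("R", "FR"), , drop = FALSE]
  half <- ci_ms / 2000
  ev <- if ("event_id" %in% names(hfo)) hfo$event_id else seq_len(nrow(hfo))
  ci <- data.frame(event_id = ev, class_id = hfo$class_id, kind = hfo$kind,
                   t_center_s = hfo$t_center_s,
                   lo = hfo$t_center_s - half, hi = hfo$t_center_s + half)
  ci <- ci[order(ci$t_center_s), , drop = FALSE]
  rownames(ci) <- NULL
  # co-occurring components of one composite event overlap by design; CIs
  # of distinct events must not (generator spacing guarantee)
  if (nrow(ci) > 1L) {
    ov <- ci$lo[-1] < ci$hi[-nrow(ci)] &
      ci$event_id[-1] != ci$event_id[-nrow(ci)]
    if (any(ov))
      stop("overlapping confidence intervals from distinct ground-truth events; generator spacing violated",
           call. = FALSE)
  }
  nd <- if (is.null(detections)) 0L else nrow(detections)
  assignment <- rep(NA_integer_, nd)
  if (nd > 0L && nrow(ci) > 0L) {
    for (d in seq_len(nd)) {
      ov <- which(detections$t_start_s[d] < ci$hi &
                    detections$t_end_s[d] > ci$lo)
      if (length(ov)) {
        mid <- (detections$t_start_s[d] + detections$t_end_s[d]) / 2
        assignment[d] <- ov[which.min(abs(ci$t_center_s[ov] - mid))]
      }
    }
  }
  matched <- sort(unique(assignment[!is.na(assignment)]))
  ci$matched <- seq_len(nrow(ci)) %in% matched
  structure(list(TP = length(matched),
                 FN = nrow(ci) - length(matched),
                 FP = sum(is.na(assignment)),
                 ci_table = ci, assignment = assignment),
            class = "match_result")
}

#' Sensitivity, precision and F-measure
#'
#' `Sens = TP/(TP+FN)`, `Prec = TP/(TP+FP)`, `F = 2 P S / (P + S)`.
#' With no detections at all, precision (and hence F) is undefined and
#' reported as `NA` rather than imputed; sensitivity is 0 when `TP = 0`
#' with positives present.
#'
#' @param m A `match_result` (or a list with `TP`, `FP`, `FN`).
#' @return Named list `sens`, `prec`, `f`.
#' @export
compute_metrics <- function(m) {
  TP <- m$TP; FP <- m$FP; FN <- m$FN
  if (any(c(TP, FP, FN) < 0)) stop("negative counts", call. = FALSE)
  sens <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  prec <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  f <- if (!is.na(sens) && !is.na(prec) && (sens + prec) > 0)
    2 * prec * sens / (prec + sens)
  else if (!is.na(sens) && !is.na(prec)) 0
  else NA_real_
  list(sens = sens, prec = prec, f = f)
}

#' Per-class sensitivity
#'
#' Sensitivity split by the 7 event classes; composite classes contribute
#' one CI per HFO component (e.g. class 4, Spk-R-FR, contributes an R CI
#' and an FR CI). Classes with no inserted HFO are reported as `NA`.
#'
#' @param m A `match_result` from [match_detections()].
#' @return data.frame with `class_id`, `label`, `n_ci`, `n_matched`,
#'   `sensitivity`.
#' @export
per_class_sensitivity <- function(m) {
  stopifnot(inherits(m, "match_result"))
  ci <- m$ci_table
  if (nrow(ci) && any(!ci$class_id %in% 1:7))
    stop("unknown class id in ground truth", call. = FALSE)
  out <- data.frame(class_id = 2:7,
                    label = CLASS_LABELS[2:7],
                    n_ci = NA_integer_, n_matched = NA_integer_,
                    sensitivity = NA_real_)
  for (i in seq_len(nrow(out))) {
    sel <- ci$class_id == out$class_id[i]
    out$n_ci[i] <- sum(sel)
    out$n_matched[i] <- sum(ci$matched[sel])
    out$sensitivity[i] <- if (out$n_ci[i] > 0)
      out$n_matched[i] / out$n_ci[i] else NA_real_
  }
  out
}

#' Score a set of records
#'
#' Aggregates matches over a benchmark: one row per
#' (detector, channel, snr, realization) with counts, metrics and the
#' detector's reported threshold, plus pooled per-class sensitivity tables.
#'
#' @param results List of records; each element needs `channel`, `snr_db`,
#'   `realization`, `detector`, `ground_truth`, `detections` (and optionally
#'   `threshold`).
#' @param ci_ms CI width (ms).
#' @return A `performance_report`: list with `records` (per-record metric
#'   data.frame), `by_snr` (pooled counts and metrics per detector x SNR)
#'   and `per_class` (pooled per detector x SNR x class).
#' @export
benchmark_report <- function(results, ci_ms = 100) {
  rec <- lapply(results, function(r) {
    m <- match_detections(r$ground_truth, r$detections, ci_ms)
    met <- compute_metrics(m)
    pc <- per_class_sensitivity(m)
    kinds <- m$ci_table$kind
    data.frame(detector = r$detector, channel = r$channel,
               snr_db = r$snr_db, realization = r$realization,
               TP = m$TP, FP = m$FP, FN = m$FN,
               sens = met$sens, prec = met$prec, f = met$f,
               threshold = if (!is.null(r$threshold)) r$threshold else NA_real_,
               mode = if (!is.null(r$mode)) r$mode else NA_character_,
               tp_r = sum(m$ci_table$matched[kinds == "R"]),
               n_r = sum(kinds == "R"),
               tp_fr = sum(m$ci_table$matched[kinds == "FR"]),
               n_fr = sum(kinds == "FR"),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rec)
  pcs <- lapply(seq_along(results), function(i) {
    m <- match_detections(results[[i]]$ground_truth,
                          results[[i]]$detections, ci_ms)
    pc <- per_class_sensitivity(m)
    pc$detector <- results[[i]]$detector
    pc$snr_db <- results[[i]]$snr_db
    pc
  })
  pcall <- do.call(rbind, pcs)
  per_class <- stats::aggregate(cbind(n_ci, n_matched) ~
                                  detector + snr_db + class_id + label,
                                data = pcall, FUN = sum)
  per_class$sensitivity <- ifelse(per_class$n_ci > 0,
                                  per_class$n_matched / per_class$n_ci, NA)
  agg <- stats::aggregate(cbind(TP, FP, FN, tp_r, n_r, tp_fr, n_fr) ~
                            detector + snr_db, data = records, FUN = sum)
  agg$sens <- ifelse(agg$TP + agg$FN > 0, agg$TP / (agg$TP + agg$FN), NA)
  agg$prec <- ifelse(agg$TP + agg$FP > 0, agg$TP / (agg$TP + agg$FP), NA)
  agg$f <- ifelse(!is.na(agg$sens) & !is.na(agg$prec) &
                    (agg$sens + agg$prec) > 0,
                  2 * agg$sens * agg$prec / (agg$sens + agg$prec), NA)
  structure(list(records = records, by_snr = agg, per_class = per_class),
            class = "performance_report")
}

#' Write a performance report as TSV/JSON files
#' @param report A `performance_report`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$records, file.path(dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$per_class, file.path(dir, "per_class.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(report$records[, c("detector", "channel", "snr_db",
                                        "realization", "threshold")],
                     file.path(dir, "thresholds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(by_snr = report$by_snr),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
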