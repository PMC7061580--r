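# Serialization of traces, feature tables and classification reports.
# Traces travel as a two-column CSV (time_s, intensity) plus a JSON sidecar
# holding the acquisition metadata; numbers are written with full precision
# so a round trip is lossless to the printed digits.

fmt_num <- function(x) sprintf("%.15g", x)

#' Write / read a signal trace as CSV + JSON sidecar
#'
#' `write_trace` produces `<stem>.csv` (columns `time_s,intensity`) and
#' `<stem>.json` (voc, thickness_um, replicate_id, seed, sampling_hz);
#' `read_trace` reverses it.
#'
#' @param trace a [signal_trace].
#' @param stem path without extension.
#' @return `write_trace`: the stem, invisibly.  `read_trace`: a
#'   [signal_trace].
#' @export
write_trace <- function(trace, stem) {
  stopifnot(inherits(trace, "signal_trace"))
  tm <- (seq_along(trace$values) - 1) / trace$sampling_hz
  df <- data.frame(time_s = fmt_num(tm), intensity = fmt_num(trace$values))
  write.csv(df, paste0(stem, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- list(voc = trace$voc, thickness_um = trace$thickness_um,
               replicate_id = trace$replicate_id, seed = trace$seed,
               sampling_hz = trace$sampling_hz)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(stem)
}

#' @rdname write_trace
#' @export
read_trace <- function(stem) {
  df <- read.csv(paste0(stem, ".csv"))
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  signal_trace(df$intensity, sampling_hz = meta$sampling_hz,
               voc = meta$voc, thickness_um = meta$thickness_um,
               replicate_id = meta$replicate_id, seed = meta$seed)
}

#' Write / read a per-cycle feature table
#'
#' One CSV row per cycle: `voc, thickness_um, replicate_id, cycle_index,
#' f1..f12`.  Feature values are written with full precision so identical
#' runs produce byte-identical files.
#'
#' @param feature_table data.frame from [extract_feature_table()].
#' @param path CSV path.
#' @return `write_feature_table`: path, invisibly; `read_feature_table`:
#'   the data.frame.
#' @export
write_feature_table <- function(feature_table, path) {
  out <- feature_table
  for (cn in paste0("f", 1:12)) out[[cn]] <- fmt_num(out[[cn]])
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a classification report to disk
#'
#' Emits `<stem>_confusion.csv` (row-normalized confusion matrix with
#' labeled rows/columns) and `<stem>_metrics.json` with thickness, pooled and
#' fold-averaged accuracy, macro/micro precision and per-VOC accuracy.
#'
#' @param report a `classification_report` from [summarize_report()].
#' @param stem output path stem.
#' @return The stem, invisibly.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "classification_report"))
  conf <- as.data.frame(report$confusion)
  conf <- cbind(true_voc = rownames(report$confusion), conf)
  write.csv(conf, paste0(stem, "_confusion.csv"), row.names = FALSE)
  metrics <- list(
    thickness_um = report$thickness_um,
    overall_accuracy = report$overall_accuracy,
    mean_fold_accuracy = report$mean_fold_accuracy,
    macro_precision = report$macro_precision,
    micro_precision = report$micro_precision,
    per_voc_accuracy = as.list(report$per_voc_accuracy),
    never_predicted = report$never_predicted
  )
  jsonlite::write_json(metrics, paste0(stem, "_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(stem)
}
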