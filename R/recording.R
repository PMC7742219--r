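#' Multichannel EMG recording
#'
#' Container for a multichannel surface-EMG recording: a channels-by-samples
#' numeric matrix, its sampling rate, channel labels, and a marker table that
#' assigns sample windows to (trial, movement period) pairs.
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz (> 0).
#' @param labels character vector of unique channel names, one per row.
#' @param markers `data.frame` with columns `trial`, `period`, `onset_sample`
#'   (1-based), `duration_samples`; may be `NULL` for an unsegmented recording.
#' @param provenance list of processing-step records carried along the chain.
#'
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, labels = rownames(samples),
                          markers = NULL, provenance = list()) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("`samples` must be a numeric matrix")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(samples)))
  labels <- as.character(labels)
  if (length(labels) != nrow(samples)) {
    stop("`labels` must have one entry per channel (matrix row)")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be > 0")
  if (!is.null(markers)) {
    markers <- as.data.frame(markers)
    need <- c("trial", "period", "onset_sample", "duration_samples")
    if (!all(need %in% names(markers))) {
      stop("markers need columns: ", paste(need, collapse = ", "))
    }
    ends <- markers$onset_sample + markers$duration_samples - 1
    if (any(markers$onset_sample < 1) || any(ends > ncol(samples))) {
      stop_imcoh("marker_range", "marker window extends beyond the recording")
    }
  }
  rownames(samples) <- labels
  structure(
    list(samples = samples, fs = fs, labels = labels, markers = markers,
         provenance = provenance),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  if (!is.null(x$markers)) {
    cat(sprintf("  markers: %d windows, periods: %s\n", nrow(x$markers),
                paste(unique(x$markers$period), collapse = ", ")))
  }
  n_steps <- length(x$provenance)
  if (n_steps) {
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  }
  invisible(x)
}

# package error helper: condition classes "imcoh_<what>"
stop_imcoh <- function(what, msg, ...) {
  stop(structure(
    class = c(paste0("imcoh_", what), "imcoh_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Write / read a recording as TSV
#'
#' The signal file has one column per channel with the channel labels as
#' header; the marker file has columns `trial`, `period`, `onset_sample`,
#' `duration_samples`. The sampling rate is stored in a one-line `#fs=` comment
#' at the top of the signal file.
#'
#' @param rec an [emg_recording].
#' @param signal_path,marker_path output/input file paths; `marker_path` may be
#'   `NULL` when the recording has no markers.
#' @return `write_recording_tsv` returns `rec` invisibly; `read_recording_tsv`
#'   returns an [emg_recording].
#' @export
write_recording_tsv <- function(rec, signal_path, marker_path = NULL) {
  stopifnot(inherits(rec, "emg_recording"))
  con <- file(signal_path, "w")
  writeLines(sprintf("#fs=%.10g", rec$fs), con)
  close(con)
  data.table::fwrite(as.data.frame(t(rec$samples)), signal_path, sep = "\t",
                     append = TRUE, col.names = TRUE)
  if (!is.null(rec$markers) && !is.null(marker_path)) {
    data.table::fwrite(rec$markers, marker_path, sep = "\t")
  }
  invisible(rec)
}

#' @rdname write_recording_tsv
#' @export
read_recording_tsv <- function(signal_path, marker_path = NULL) {
  first <- readLines(signal_path, n = 1L)
  if (!grepl("^#fs=", first)) stop("signal TSV must start with a '#fs=' line")
  fs <- as.numeric(sub("^#fs=", "", first))
  dt <- data.table::fread(signal_path, sep = "\t", skip = 1L, header = TRUE)
  markers <- if (!is.null(marker_path)) {
    as.data.frame(data.table::fread(marker_path, sep = "\t"))
  }
  emg_recording(t(as.matrix(dt)), fs = fs, labels = names(dt),
                markers = markers)
}

add_provenance <- function(rec, step, ...) {
  rec$provenance <- c(rec$provenance, list(c(list(step = step), list(...))))
  rec
}

# homologous-pair helpers: "VL_l" -> pair "VL", side "l"
pair_of <- function(label) sub("_[lr]$", "", label)
side_of <- function(label) sub("^.*_([lr])$", "\\1", label)
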