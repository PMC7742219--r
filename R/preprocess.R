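#' Decimate a recording with Chebyshev anti-alias filtering
#'
#' Low-pass filters each channel with a Chebyshev Type I filter (order 8,
#' 0.05 dB passband ripple, corner at `cutoff` Hz, rescaled to exactly unit DC
#' gain) applied forward-backward (zero phase), then keeps every k-th sample,
#' where `k = fs / target_fs` must be an integer. Markers are rescaled to the
#' new rate.
#'
#' @param rec an [emg_recording].
#' @param target_fs output sampling rate in Hz (default 500).
#' @param cutoff anti-alias corner frequency in Hz (default 200).
#' @param order,ripple_db Chebyshev design parameters.
#' @return The decimated [emg_recording].
#' @export
decimate_recording <- function(rec, target_fs = 500, cutoff = 200,
                               order = 8, ripple_db = 0.05) {
  stopifnot(inherits(rec, "emg_recording"))
  k <- rec$fs / target_fs
  if (abs(k - round(k)) > 1e-9 || k < 1) {
    stop_imcoh("unsupported_rate",
               "fs (%g) must be an integer multiple of target_fs (%g)",
               rec$fs, target_fs)
  }
  k <- as.integer(round(k))
  if (k == 1L) return(add_provenance(rec, "decimate", factor = 1L))
  flt <- signal::cheby1(order, ripple_db, cutoff / (rec$fs / 2), type = "low")
  flt$b <- flt$b * (sum(flt$a) / sum(flt$b))   # pin DC gain to exactly 1
  keep <- seq(1, ncol(rec$samples), by = k)
  out <- matrix(0, nrow(rec$samples), length(keep),
                dimnames = list(rec$labels, NULL))
  for (i in seq_len(nrow(rec$samples))) {
    out[i, ] <- signal::filtfilt(flt, rec$samples[i, ])[keep]
  }
  markers <- rec$markers
  if (!is.null(markers)) {
    markers$onset_sample <- (markers$onset_sample - 1L) %/% k + 1L
    markers$duration_samples <- markers$duration_samples %/% k
  }
  rec2 <- emg_recording(out, fs = target_fs, labels = rec$labels,
                        markers = markers, provenance = rec$provenance)
  add_provenance(rec2, "decimate", factor = k, cutoff_hz = cutoff,
                 filter = sprintf("cheby1(order=%d, ripple=%g dB), zero-phase",
                                  order, ripple_db))
}

#' High-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth high-pass, applied per channel.
#'
#' @param rec an [emg_recording].
#' @param cutoff corner frequency in Hz (default 20); must be below Nyquist.
#' @param order filter order (default 4).
#' @return The filtered [emg_recording].
#' @export
highpass_recording <- function(rec, cutoff = 20, order = 4) {
  stopifnot(inherits(rec, "emg_recording"))
  if (cutoff >= rec$fs / 2) {
    stop_imcoh("invalid_cutoff", "cutoff (%g Hz) must be below Nyquist (%g Hz)",
               cutoff, rec$fs / 2)
  }
  flt <- signal::butter(order, cutoff / (rec$fs / 2), type = "high")
  for (i in seq_len(nrow(rec$samples))) {
    # demean before filtering (smaller edge transients) and after (the DC
    # bin is deep in the stopband; remove the residual numerical offset)
    y <- signal::filtfilt(flt, rec$samples[i, ] - mean(rec$samples[i, ]))
    rec$samples[i, ] <- y - mean(y)
  }
  add_provenance(rec, "highpass", cutoff_hz = cutoff,
                 filter = sprintf("butter(order=%d), zero-phase", order))
}

# analytic signal via frequency-domain Hilbert transformer
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Hilbert envelope (EMG rectification)
#'
#' Replaces each channel by the magnitude of its analytic signal. Applied to
#' the continuous recording (before epoching) so that analytic-signal edge
#' effects occur only at the recording ends; the first/last 100 ms are flagged
#' in provenance.
#'
#' @param rec an [emg_recording].
#' @return The envelope [emg_recording]; all values are nonnegative.
#' @export
hilbert_envelope <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  if (any(!is.finite(rec$samples))) stop("samples must be finite")
  for (i in seq_len(nrow(rec$samples))) {
    rec$samples[i, ] <- Mod(analytic_signal(rec$samples[i, ]))
  }
  add_provenance(rec, "hilbert_envelope",
                 edge_flag_ms = 100,
                 note = "first/last 100 ms subject to analytic-signal edge effects")
}

#' Epoch a recording into per-period trials
#'
#' Cuts the (envelope) recording into one epoch per marker row, grouped by
#' movement period. Epochs within a period must have a common duration and
#' every period the same trial count; the concatenation order is trial order.
#'
#' @param rec an [emg_recording] with markers.
#' @return An object of class `epoched_envelopes`: list with `epochs` (named
#'   list period -> list of channels x samples matrices), `fs`, `labels`,
#'   `provenance`.
#' @export
epoch_envelopes <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  mk <- rec$markers
  if (is.null(mk) || nrow(mk) == 0) {
    stop_imcoh("empty_markers", "recording has no markers to epoch by")
  }
  ends <- mk$onset_sample + mk$duration_samples - 1
  if (any(mk$onset_sample < 1) || any(ends > ncol(rec$samples))) {
    stop_imcoh("marker_range", "marker window extends beyond the recording")
  }
  periods <- unique(mk$period)
  epochs <- lapply(periods, function(p) {
    rows <- mk[mk$period == p, , drop = FALSE]
    rows <- rows[order(rows$trial), , drop = FALSE]
    if (length(unique(rows$duration_samples)) != 1) {
      stop_imcoh("inconsistent_epoch",
                 "unequal epoch durations within period %s", p)
    }
    lapply(seq_len(nrow(rows)), function(i) {
      sel <- rows$onset_sample[i] + seq_len(rows$duration_samples[i]) - 1
      rec$samples[, sel, drop = FALSE]
    })
  })
  names(epochs) <- periods
  counts <- vapply(epochs, length, 0L)
  if (length(unique(counts)) != 1) {
    stop_imcoh("inconsistent_epoch",
               "unequal trial counts across periods: %s",
               paste(sprintf("%s=%d", periods, counts), collapse = ", "))
  }
  structure(
    list(epochs = epochs, fs = rec$fs, labels = rec$labels,
         provenance = c(rec$provenance,
                        list(list(step = "epoch", n_trials = counts[[1]],
                                  order = "trial order")))),
    class = "epoched_envelopes"
  )
}

#' @export
print.epoched_envelopes <- function(x, ...) {
  lens <- vapply(x$epochs, function(e) ncol(e[[1]]), 0L)
  cat(sprintf("<epoched_envelopes> %d periods x %d trials, %d channels @ %g Hz\n",
              length(x$epochs), length(x$epochs[[1]]), length(x$labels), x$fs))
  cat("  periods:", paste(sprintf("%s (%d samples)", names(x$epochs), lens),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Preprocess a raw recording into envelope epochs
#'
#' Fixed chain: decimate (Chebyshev anti-alias, default to 500 Hz) ->
#' Butterworth high-pass (default 20 Hz) -> Hilbert envelope -> epoch by
#' markers. Both filters are zero-phase so downstream phase-slope delay
#' estimates are not biased by filter group delay.
#'
#' @param rec a raw [emg_recording] with markers.
#' @param target_fs,hp_cutoff working rate and high-pass corner (Hz).
#' @return list with `epochs` (an `epoched_envelopes`) and `filtered` (the
#'   decimated, high-passed [emg_recording] prior to envelope extraction,
#'   used for amplitude/RMS analyses).
#' @export
preprocess_recording <- function(rec, target_fs = 500, hp_cutoff = 20) {
  dec <- decimate_recording(rec, target_fs = target_fs)
  hp <- highpass_recording(dec, cutoff = hp_cutoff)
  env <- hilbert_envelope(hp)
  list(epochs = epoch_envelopes(env), filtered = hp)
}
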