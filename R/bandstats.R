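#' Assign frequency bins to bands
#'
#' Bins with `low <= f <= high` belong to a band; where two bands share an
#' edge frequency, the shared bin is assigned to the higher band only (so with
#' the defaults at 2-Hz resolution: alpha {8, 10, 12}, beta {14, ..., 28},
#' gamma {30, ..., 44} - the 30-Hz bin counts once, in gamma).
#'
#' @param freqs frequency grid in Hz.
#' @param band_defs named list of `c(low, high)` intervals.
#' @return named list of integer bin-index vectors.
#' @export
band_bins <- function(freqs, band_defs) {
  ord <- order(vapply(band_defs, `[`, 0, 1))
  defs <- band_defs[ord]
  out <- lapply(defs, function(b) {
    which(freqs >= b[1] - 1e-9 & freqs <= b[2] + 1e-9)
  })
  for (i in seq_along(defs)[-length(defs)]) {
    nxt_low <- defs[[i + 1]][1]
    out[[i]] <- setdiff(out[[i]], which(abs(freqs - nxt_low) < 1e-9))
  }
  out[names(band_defs)]
}

#' Band-summed significant coherence (IMC area)
#'
#' Sums magnitude-squared coherence over the band bins where it exceeds the
#' significance limit; bins at or below the limit contribute nothing. This is
#' the primary summary statistic of the workflow, preferred to peak
#' coherence. The `"excess"` variant sums `coherence - CL` at significant
#' bins instead.
#'
#' @param coh a `coherence_spectrum`.
#' @param band Hz interval `c(low, high)`.
#' @param bins optional explicit bin indices (e.g. from [band_bins()] with
#'   the shared-edge rule); overrides `band`.
#' @param variant `"coherence"` (default: sum raw coherence at significant
#'   bins) or `"excess"`.
#' @return list with `imc_area` (>= 0) and `n_sig_bins`.
#' @export
imc_area <- function(coh, band, bins = NULL,
                     variant = c("coherence", "excess")) {
  variant <- match.arg(variant)
  stopifnot(inherits(coh, "coherence_spectrum"))
  if (is.null(bins)) {
    bins <- which(coh$freqs >= band[1] - 1e-9 & coh$freqs <= band[2] + 1e-9)
  }
  if (!length(bins)) stop("band contains no frequency bins")
  cv <- coh$coherence[bins]
  sig <- cv > coh$cl
  area <- if (variant == "excess") sum(cv[sig] - coh$cl) else sum(cv[sig])
  list(imc_area = area, n_sig_bins = sum(sig))
}

#' Tabulate IMC area across pairs, periods and bands
#'
#' @param spectra list of `coherence_spectrum` objects (one per pair x
#'   period); pair rows are labelled by the shared muscle name (e.g. "VL"
#'   for the VL_l / VL_r pair).
#' @param band_defs named list of band intervals; bins assigned with the
#'   shared-edge rule of [band_bins()].
#' @param subject subject identifier for the rows.
#' @param variant passed to [imc_area()].
#' @return `data.frame` with columns subject, pair, period, band, imc_area,
#'   n_sig_bins.
#' @export
imc_area_table <- function(spectra, band_defs, subject = 1,
                           variant = "coherence") {
  rows <- lapply(spectra, function(cs) {
    bb <- band_bins(cs$freqs, band_defs)
    do.call(rbind, lapply(names(bb), function(b) {
      a <- imc_area(cs, band = band_defs[[b]], bins = bb[[b]],
                    variant = variant)
      data.frame(subject = subject, pair = pair_of(cs$pair[1]),
                 period = cs$period, band = b, imc_area = a$imc_area,
                 n_sig_bins = a$n_sig_bins, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log-transform an IMC-area table
#'
#' Adds `log_imc_area = log(imc_area + offset)`; the additive offset floors
#' empty cells (zero area) at `log(offset)` and is recorded as an attribute.
#'
#' @param table a `data.frame` with an `imc_area` column.
#' @param offset positive additive offset (default 1e-6).
#' @return The table with a `log_imc_area` column and attribute
#'   `log_offset`.
#' @export
log_transform_table <- function(table, offset = 1e-6) {
  if (!"imc_area" %in% names(table)) stop("table needs an `imc_area` column")
  if (any(table$imc_area < 0)) {
    stop_imcoh("corrupted_table", "negative imc_area values present")
  }
  stopifnot(offset > 0)
  table$log_imc_area <- log(table$imc_area + offset)
  attr(table, "log_offset") <- offset
  table
}

#' Windowed-RMS activation ratios per muscle and period
#'
#' For each channel, computes the RMS over consecutive non-overlapping
#' windows (trailing partial windows discarded) inside every marked period
#' window, normalizes by the channel's maximum window RMS over the entire
#' recording (activation ratio), and averages per period.
#'
#' @param rec an [emg_recording] with markers (typically the decimated,
#'   high-passed recording).
#' @param window_ms RMS window length in milliseconds (default 50).
#' @return `data.frame` with columns muscle, period, rms_mean (in \[0, 1\]).
#' @export
rms_activation <- function(rec, window_ms = 50) {
  stopifnot(inherits(rec, "emg_recording"))
  mk <- rec$markers
  if (is.null(mk) || nrow(mk) == 0) {
    stop_imcoh("empty_markers", "recording has no markers")
  }
  wlen <- max(1L, round(window_ms / 1000 * rec$fs))
  if (any(mk$duration_samples < wlen)) {
    stop("RMS window longer than a period window")
  }
  periods <- unique(mk$period)
  nch <- nrow(rec$samples)
  # window RMS values per channel, grouped by period
  vals <- lapply(seq_len(nch), function(ch) {
    lapply(periods, function(p) {
      rows <- mk[mk$period == p, , drop = FALSE]
      unlist(lapply(seq_len(nrow(rows)), function(i) {
        n_win <- rows$duration_samples[i] %/% wlen
        sel <- rows$onset_sample[i] + seq_len(n_win * wlen) - 1
        seg <- rec$samples[ch, sel]
        sqrt(colMeans(matrix(seg^2, nrow = wlen)))
      }))
    })
  })
  out <- do.call(rbind, lapply(seq_len(nch), function(ch) {
    mx <- max(unlist(vals[[ch]]))
    if (mx == 0) {
      stop_imcoh("undefined_normalization",
                 "channel %s is all zero; activation ratio undefined",
                 rec$labels[ch])
    }
    data.frame(muscle = rec$labels[ch], period = periods,
               rms_mean = vapply(vals[[ch]], function(v) mean(v) / mx, 0),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_windows") <- vapply(periods, function(p) {
    sum(mk$duration_samples[mk$period == p] %/% wlen)
  }, 0)
  attr(out, "window_samples") <- wlen
  out
}

#' Normalize auto-spectra to total power
#'
#' Divides each channel's PSD by its summed power so every column sums to 1
#' over the frequency grid (scale-invariant spectral shape).
#'
#' @param grid a `spectral_grid`.
#' @return bins x channels matrix of normalized PSD values.
#' @export
normalize_psd <- function(grid) {
  stopifnot(inherits(grid, "spectral_grid"))
  tot <- colSums(grid$S_auto)
  if (any(tot <= 0)) {
    stop_imcoh("degenerate_spectrum",
               "zero total power in channel %s",
               grid$labels[which(tot <= 0)[1]])
  }
  sweep(grid$S_auto, 2, tot, "/")
}
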