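#' Periodic Hann window
#' @param n window length in samples.
#' @return numeric vector of window weights.
#' @keywords internal
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

# squared normalized window autocorrelations at multiples of the step; these
# drive the variance-reduction ("effective segments") overlap adjustment
window_overlap_corr <- function(w, step) {
  L <- length(w)
  sw2 <- sum(w^2)
  m <- 1L
  cm <- numeric(0)
  while (m * step < L) {
    lag <- m * step
    cm[m] <- (sum(w[1:(L - lag)] * w[(lag + 1):L]) / sw2)^2
    m <- m + 1L
  }
  cm
}

# effective number of independent segments for one contiguous block:
# K / (1 + 2 * sum((1 - m/K) c_m)), the usual equivalent-degrees-of-freedom
# count for averaged overlapping windowed periodograms
effective_segments_block <- function(len, L, step, w = hann_window(L)) {
  if (len < L) return(0)
  K <- floor((len - L) / step) + 1
  cm <- window_overlap_corr(w, step)
  if (length(cm)) {
    m <- seq_along(cm)
    keep <- m < K
    K / (1 + 2 * sum((1 - m[keep] / K) * cm[keep]))
  } else {
    K
  }
}

#' Welch auto- and cross-spectra of concatenated envelope epochs
#'
#' Estimates one-sided auto-spectral densities for every channel and
#' cross-spectral densities for every channel pair of one movement period by
#' averaging Hann-windowed, per-segment mean-removed periodograms across all
#' segments of all epochs. Segments never span epoch (trial-concatenation)
#' boundaries. With the defaults (500-ms window, 75% overlap) the frequency
#' resolution is 2 Hz and the segment step is `floor(0.25 * window)` samples.
#'
#' @param epochs an `epoched_envelopes` (see [epoch_envelopes()]), or any list
#'   shaped like it.
#' @param period period label to analyse; must name an entry of
#'   `epochs$epochs`.
#' @param window_ms Welch window length in milliseconds (default 500).
#' @param overlap fractional overlap in \[0, 1) (default 0.75).
#' @return An object of class `spectral_grid`: `freqs` (Hz), `S_auto`
#'   (bins x channels, density units), `S_cross` (complex bins x channels x
#'   channels with Hermitian symmetry), `n_segments`, `n_disjoint`,
#'   `n_effective` (overlap-adjusted effective independent segment count),
#'   plus window/overlap/rate metadata.
#' @export
welch_spectra <- function(epochs, period, window_ms = 500, overlap = 0.75) {
  eps_list <- epochs$epochs[[period]]
  if (is.null(eps_list)) stop("unknown period: ", period)
  fs <- epochs$fs
  L <- round(window_ms / 1000 * fs)
  if (!(overlap >= 0 && overlap < 1)) stop("overlap must be in [0, 1)")
  step <- max(1L, as.integer(floor(L * (1 - overlap))))
  lens <- vapply(eps_list, ncol, 0L)
  if (any(lens < L)) {
    stop_imcoh("window_too_long",
               "epoch length %d < window length %d samples", min(lens), L)
  }
  nch <- nrow(eps_list[[1]])
  labels <- epochs$labels
  w <- hann_window(L)
  nf <- L %/% 2 + 1
  scale <- 1 / (fs * sum(w^2))

  S_auto <- matrix(0, nf, nch)
  S_cross <- array(0 + 0i, c(nf, nch, nch))
  n_segments <- 0L
  for (ep in eps_list) {
    starts <- seq(1L, ncol(ep) - L + 1L, by = step)
    K <- length(starts)
    n_segments <- n_segments + K
    # windowed, mean-removed FFTs: one nf x K matrix per channel
    Fch <- vector("list", nch)
    for (ch in seq_len(nch)) {
      M <- matrix(0, L, K)
      for (s in seq_len(K)) {
        seg <- ep[ch, starts[s]:(starts[s] + L - 1L)]
        M[, s] <- (seg - mean(seg)) * w
      }
      Fch[[ch]] <- stats::mvfft(M)[1:nf, , drop = FALSE]
    }
    for (i in seq_len(nch)) {
      S_auto[, i] <- S_auto[, i] + rowSums(Mod(Fch[[i]])^2)
      for (j in i:nch) {
        S_cross[, i, j] <- S_cross[, i, j] +
          rowSums(Fch[[i]] * Conj(Fch[[j]]))
      }
    }
  }
  # average, density scaling, one-sided doubling (not DC / Nyquist)
  one_sided <- rep(2, nf)
  one_sided[1] <- 1
  if (L %% 2 == 0) one_sided[nf] <- 1
  fac <- scale / n_segments * one_sided
  S_auto <- S_auto * fac
  for (i in seq_len(nch)) {
    for (j in i:nch) {
      S_cross[, i, j] <- S_cross[, i, j] * fac
      if (j > i) S_cross[, j, i] <- Conj(S_cross[, i, j])
    }
  }
  dimnames(S_auto) <- list(NULL, labels)
  dimnames(S_cross) <- list(NULL, labels, labels)

  n_disjoint <- sum(lens %/% L)
  n_effective <- sum(vapply(lens, effective_segments_block, 0, L = L,
                            step = step, w = w))
  structure(
    list(freqs = (seq_len(nf) - 1) * fs / L, S_auto = S_auto,
         S_cross = S_cross, n_segments = n_segments,
         n_disjoint = n_disjoint, n_effective = n_effective,
         window_ms = window_ms, window_samples = L, step = step,
         overlap = overlap, fs = fs, labels = labels, period = period,
         n_epochs = length(eps_list)),
    class = "spectral_grid"
  )
}

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf(
    "<spectral_grid> period %s: %d channels, %d bins (0-%g Hz, df = %g Hz)\n",
    x$period, length(x$labels), length(x$freqs), max(x$freqs),
    x$freqs[2] - x$freqs[1]))
  cat(sprintf("  %d segments (%d disjoint, %.1f effective) of %d samples, overlap %g\n",
              x$n_segments, x$n_disjoint, x$n_effective, x$window_samples,
              x$overlap))
  invisible(x)
}

#' Wrap plain signals as single-epoch envelope containers
#'
#' Convenience for spectral analysis of signals that are not organised in
#' trials (e.g. the linear common-input oracle model): stacks the vectors as
#' channels of one epoch under one period label.
#'
#' @param ... named numeric vectors of equal length (channel signals).
#' @param fs sampling rate in Hz.
#' @param period period label (default "ALL").
#' @return An `epoched_envelopes` with a single epoch.
#' @export
as_epochs <- function(..., fs, period = "ALL") {
  sig <- list(...)
  if (length(sig) == 1 && is.list(sig[[1]]) && !is.numeric(sig[[1]])) {
    sig <- sig[[1]]
  }
  if (is.null(names(sig)) || any(names(sig) == "")) {
    names(sig) <- paste0("ch", seq_along(sig))
  }
  mat <- do.call(rbind, sig)
  eps <- stats::setNames(list(list(mat)), period)
  structure(list(epochs = eps, fs = fs, labels = names(sig),
                 provenance = list()),
            class = "epoched_envelopes")
}
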