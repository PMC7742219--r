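#' Coherence significance limit
#'
#' Threshold above which magnitude-squared coherence is deemed significant at
#' level `alpha`, for a Welch estimate averaged over `N` independent segments:
#' `CL = 1 - alpha^(1/(N - 1))` (the Rosenberg-type limit, derived from the
#' null distribution `P(C > c) = (1 - c)^(N - 1)`). With overlapping segments
#' the averaged periodograms are correlated; `N` is then replaced by an
#' effective independent-segment count computed from the squared window
#' autocorrelations at multiples of the step (for a Hann window at 75%
#' overlap the inflation over the disjoint count is about 1.94).
#'
#' The `"printed"` variant `1 - (1 - alpha)^(1/(N - 1))` is provided for
#' comparison only; it is severely anticonservative (it declares nearly every
#' bin significant) and fails Monte-Carlo type-I calibration.
#'
#' @param n_disjoint number of non-overlapping window-length segments that fit
#'   the data (>= 2).
#' @param overlap fractional segment overlap in \[0, 1).
#' @param alpha significance level in (0, 0.5].
#' @param window_length window length in samples used for the overlap
#'   correction (the correction depends only on the step/window ratio;
#'   default 250).
#' @param n_blocks number of contiguous blocks (epochs) the `n_disjoint`
#'   segments are spread over; segments do not run across block joins.
#' @param variant `"rosenberg"` (default) or `"printed"`.
#' @return list with `cl` (the confidence limit in (0,1)) and `n_effective`.
#' @export
confidence_limit <- function(n_disjoint, overlap = 0, alpha = 0.05,
                             window_length = 250, n_blocks = 1,
                             variant = c("rosenberg", "printed")) {
  variant <- match.arg(variant)
  if (n_disjoint < 2) {
    stop_imcoh("insufficient_segments",
               "need at least 2 disjoint segments, got %g", n_disjoint)
  }
  stopifnot(alpha > 0, alpha <= 0.5, overlap >= 0, overlap < 1)
  if (overlap == 0) {
    n_eff <- n_disjoint
  } else {
    L <- window_length
    step <- max(1L, as.integer(floor(L * (1 - overlap))))
    per_block <- n_disjoint / n_blocks
    n_eff <- n_blocks *
      effective_segments_block(round(per_block * L), L, step)
  }
  list(cl = cl_from_neff(n_eff, alpha, variant), n_effective = n_eff)
}

cl_from_neff <- function(n_eff, alpha, variant = "rosenberg") {
  if (variant == "printed") {
    1 - (1 - alpha)^(1 / (n_eff - 1))
  } else {
    1 - alpha^(1 / (n_eff - 1))
  }
}

#' Magnitude-squared coherence between two channels
#'
#' `C(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f))` with phase `arg S_xy(f)`,
#' evaluated on a [welch_spectra()] grid, together with the significance
#' limit computed from the grid's overlap-adjusted effective segment count.
#' Positive phase slope means the first channel leads.
#'
#' @param grid a `spectral_grid`.
#' @param pair length-2 vector of channel labels or indices.
#' @param alpha significance level for the confidence limit.
#' @param variant confidence-limit formula, see [confidence_limit()].
#' @return An object of class `coherence_spectrum`: `freqs`, `coherence` in
#'   \[0,1\], `phase` in (-pi, pi\], `cl`, `alpha`, `n_effective`,
#'   `n_disjoint`, `n_segments`, `pair`, `period`.
#' @export
coherence <- function(grid, pair, alpha = 0.05,
                      variant = c("rosenberg", "printed")) {
  variant <- match.arg(variant)
  stopifnot(inherits(grid, "spectral_grid"), length(pair) == 2)
  idx <- if (is.character(pair)) match(pair, grid$labels) else as.integer(pair)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > length(grid$labels))) {
    stop("pair channels not found in grid: ", paste(pair, collapse = ", "))
  }
  if (grid$n_segments < 2) {
    stop_imcoh("insufficient_segments", "need at least 2 averaged segments")
  }
  Sxx <- grid$S_auto[, idx[1]]
  Syy <- grid$S_auto[, idx[2]]
  bad <- which(Sxx == 0 | Syy == 0)
  if (length(bad)) {
    stop_imcoh("degenerate_spectrum",
               "zero auto-spectrum at bin %d (%g Hz)", bad[1],
               grid$freqs[bad[1]])
  }
  Sxy <- grid$S_cross[, idx[1], idx[2]]
  coh <- Mod(Sxy)^2 / (Sxx * Syy)
  # guard round-off only; genuine values never exceed 1
  coh <- pmin(pmax(coh, 0), 1 + 1e-12)
  coh[coh > 1] <- 1
  structure(
    list(freqs = grid$freqs, coherence = coh, phase = Arg(Sxy),
         cl = cl_from_neff(grid$n_effective, alpha, variant), alpha = alpha,
         n_effective = grid$n_effective, n_disjoint = grid$n_disjoint,
         n_segments = grid$n_segments, pair = grid$labels[idx],
         period = grid$period, fs = grid$fs, window_ms = grid$window_ms),
    class = "coherence_spectrum"
  )
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %s - %s (period %s)\n",
              x$pair[1], x$pair[2], x$period))
  cat(sprintf("  %d bins, CL(alpha=%g) = %.4g, %.1f effective segments\n",
              length(x$freqs), x$alpha, x$cl, x$n_effective))
  cat(sprintf("  peak coherence %.3f at %g Hz\n", max(x$coherence),
              x$freqs[which.max(x$coherence)]))
  invisible(x)
}

# phase unwrapping (cumulative 2*pi correction)
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  corr <- cumsum(round(dp / (2 * pi)))
  p - c(0, corr * 2 * pi)
}

#' Phase-slope time delay over a frequency band
#'
#' Unwraps the cross-spectral phase over the band bins and fits an ordinary
#' (optionally coherence-weighted) least-squares line of phase against
#' frequency. The temporal delay is the slope divided by 2*pi, reported in
#' milliseconds; positive values mean the first channel of the pair leads.
#'
#' @param coh a `coherence_spectrum`.
#' @param band Hz interval `c(low, high)`; must contain at least 3 bins.
#' @param band_label optional name carried into the result.
#' @param weighted if `TRUE`, weight bins by their coherence.
#' @return An object of class `delay_estimate`: `band`, `slope` (rad/Hz),
#'   `delay_ms`, `r_squared`, `n_bins`, `pair`, `period`.
#' @export
estimate_delay <- function(coh, band, band_label = NULL, weighted = FALSE) {
  stopifnot(inherits(coh, "coherence_spectrum"), length(band) == 2)
  bins <- which(coh$freqs >= band[1] & coh$freqs <= band[2])
  if (length(bins) < 3) {
    stop_imcoh("band_too_narrow",
               "band [%g, %g] Hz has %d bins; need >= 3", band[1], band[2],
               length(bins))
  }
  f <- coh$freqs[bins]
  ph <- unwrap_phase(coh$phase[bins])
  wts <- if (weighted) coh$coherence[bins] else rep(1, length(bins))
  fit <- stats::lm.wfit(cbind(1, f), ph, wts)
  slope <- fit$coefficients[2]
  ssr <- sum(wts * fit$residuals^2)
  sst <- sum(wts * (ph - stats::weighted.mean(ph, wts))^2)
  structure(
    list(band = if (is.null(band_label)) sprintf("%g-%g Hz", band[1], band[2])
         else band_label,
         band_hz = band, slope = unname(slope),
         delay_ms = unname(slope) / (2 * pi) * 1000,
         r_squared = if (sst > 0) 1 - ssr / sst else 1,
         n_bins = length(bins), pair = coh$pair, period = coh$period),
    class = "delay_estimate"
  )
}

#' @export
print.delay_estimate <- function(x, ...) {
  cat(sprintf("<delay_estimate> %s - %s, %s: %.2f ms (slope %.4g rad/Hz, R2 %.3f, %d bins)\n",
              x$pair[1], x$pair[2], x$band, x$delay_ms, x$slope,
              x$r_squared, x$n_bins))
  invisible(x)
}
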