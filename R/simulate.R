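#' Simulation configuration for synthetic common-drive EMG
#'
#' Defines a synthetic surface-EMG acquisition in which homologous muscle
#' pairs share band-limited oscillatory drive. Defaults mirror a typical
#' bilateral squat protocol: 8 channels (left/right vastus lateralis VL,
#' vastus medialis VM, tibialis anterior TA, erector spinae ES) sampled at
#' 3,000 Hz, 40 repetitions of three 5-s movement periods (ECC, ISO, CON).
#'
#' Each channel is a band-limited carrier (surface-EMG-like interference
#' noise) multiplied by a nonnegative envelope
#' \deqn{env_m(t) = g_{m,p} \max\{0,\; 1 + \sum_b \gamma_{pair(m),p,b}
#'   d_{pair(m),b}(t - \tau_{side(m)}) + \epsilon_m(t)\}}
#' where \eqn{d} are unit-variance band-limited drives shared within a
#' homologous pair, \eqn{\gamma} are coupling gains in \[0, 1\],
#' \eqn{\tau} an inter-side drive delay, \eqn{g_{m,p}} a multiplicative
#' period-specific activation scale and \eqn{\epsilon} independent envelope
#' noise. Coupling defaults keep the clipped fraction below 1% of samples.
#'
#' @param sampling_rate Hz, default 3000.
#' @param n_trials number of repetitions, default 40.
#' @param period_labels ordered movement-period labels, default ECC, ISO, CON.
#' @param period_duration seconds per period, default 5.
#' @param muscles channel labels `<pair>_<l|r>`; default 4 homologous pairs.
#' @param band_defs named list of frequency intervals (Hz) for the drive
#'   bands; default alpha 8-12, beta 13-30, gamma 30-44.
#' @param coupling `data.frame(pair, period, band, gain)` with gains in
#'   \[0, 1\]; `NULL` builds the default scheme (ES > TA > VM > VL; beta and
#'   gamma elevated during ECC, amplitude-independent).
#' @param delay_ms named numeric, inter-side drive delay per pair in ms
#'   (positive: left leads); default 0 for every pair.
#' @param period_gain matrix muscles x periods of positive envelope scales;
#'   `NULL` gives ISO the highest activation (1.2 vs 0.8).
#' @param carrier_band Hz interval of the EMG carrier noise, default 20-200.
#' @param noise_sd standard deviation of the independent envelope noise.
#' @param seed integer master seed; expands to per-component substreams.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(sampling_rate = 3000, n_trials = 40,
                              period_labels = c("ECC", "ISO", "CON"),
                              period_duration = 5,
                              muscles = c("VL_l", "VL_r", "VM_l", "VM_r",
                                          "TA_l", "TA_r", "ES_l", "ES_r"),
                              band_defs = list(alpha = c(8, 12),
                                               beta  = c(13, 30),
                                               gamma = c(30, 44)),
                              coupling = NULL, delay_ms = NULL,
                              period_gain = NULL,
                              carrier_band = c(20, 200), noise_sd = 0.15,
                              seed = 1L) {
  pairs <- unique(pair_of(muscles))
  if (is.null(coupling)) {
    coupling <- default_coupling(pairs, period_labels, names(band_defs))
  }
  if (is.null(delay_ms)) {
    delay_ms <- stats::setNames(rep(0, length(pairs)), pairs)
  }
  if (is.null(period_gain)) {
    period_gain <- matrix(0.8, length(muscles), length(period_labels),
                          dimnames = list(muscles, period_labels))
    if ("ISO" %in% period_labels) period_gain[, "ISO"] <- 1.2
  }
  cfg <- structure(
    list(sampling_rate = sampling_rate, n_trials = as.integer(n_trials),
         period_labels = period_labels, period_duration = period_duration,
         muscles = muscles, band_defs = band_defs, coupling = coupling,
         delay_ms = delay_ms, period_gain = period_gain,
         carrier_band = carrier_band, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
  cfg
}

# default coupling: pair ordering ES > TA > VM > VL; beta/gamma highest in ECC
default_coupling <- function(pairs, periods, bands) {
  base <- c(alpha = 0.15, beta = 0.18, gamma = 0.12)
  pair_mult <- c(ES = 1.3, TA = 1.1, VM = 0.95, VL = 0.9)
  per_mult <- rbind(alpha = c(ECC = 1.0, ISO = 1.0, CON = 1.0),
                    beta  = c(ECC = 1.2, ISO = 0.9, CON = 1.0),
                    gamma = c(ECC = 1.3, ISO = 0.9, CON = 0.95))
  grid <- expand.grid(pair = pairs, period = periods, band = bands,
                      stringsAsFactors = FALSE)
  gb <- ifelse(grid$band %in% names(base), base[grid$band], 0.15)
  pm <- ifelse(grid$pair %in% names(pair_mult), pair_mult[grid$pair], 1)
  tm <- mapply(function(b, p) {
    if (b %in% rownames(per_mult) && p %in% colnames(per_mult)) {
      per_mult[b, p]
    } else 1
  }, grid$band, grid$period)
  grid$gain <- pmin(1, gb * pm * tm)
  grid
}

validate_simulation_config <- function(cfg) {
  err <- function(field, msg) {
    stop_imcoh("config", "invalid simulation config field `%s`: %s", field, msg)
  }
  if (cfg$sampling_rate <= 2 * cfg$carrier_band[2]) {
    err("sampling_rate", "must exceed twice the carrier band upper edge")
  }
  if (cfg$n_trials < 1) err("n_trials", "must be >= 1")
  if (cfg$period_duration <= 0) err("period_duration", "must be > 0")
  if (any(!grepl("_[lr]$", cfg$muscles))) {
    err("muscles", "labels must end in _l or _r")
  }
  bands <- cfg$band_defs
  edges <- do.call(rbind, bands)
  if (any(edges[, 1] >= edges[, 2])) err("band_defs", "empty interval")
  o <- order(edges[, 1])
  if (any(edges[o, 2][-length(bands)] > edges[o, 1][-1])) {
    err("band_defs", "band intervals must not overlap")
  }
  if (any(edges > 250)) {
    err("band_defs", "bands must lie below the 250 Hz post-decimation Nyquist")
  }
  if (any(cfg$coupling$gain < 0 | cfg$coupling$gain > 1)) {
    err("coupling", "gains must lie in [0, 1]")
  }
  if (any(abs(cfg$delay_ms) / 1000 >= cfg$period_duration)) {
    err("delay_ms", "|delay| must be smaller than the period duration")
  }
  if (any(cfg$period_gain <= 0)) err("period_gain", "must be > 0")
  if (cfg$noise_sd < 0) err("noise_sd", "must be >= 0")
  invisible(cfg)
}

#' Band-limited Gaussian noise
#'
#' Generates a zero-mean, unit-variance stationary signal whose power is
#' confined to `band` by zeroing out-of-band Fourier coefficients of white
#' Gaussian noise (brick-wall synthesis), then standardizing.
#'
#' @param band Hz interval `c(low, high)` strictly inside (0, fs/2).
#' @param duration seconds; must cover at least 10 cycles of `band[1]`.
#' @param fs sampling rate in Hz.
#' @param seed integer seed; identical calls are bitwise reproducible.
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
generate_band_limited_noise <- function(band, duration, fs, seed) {
  if (length(band) != 2 || band[1] <= 0 || band[2] >= fs / 2 ||
      band[1] >= band[2]) {
    stop_imcoh("invalid_band", "band must satisfy 0 < low < high < fs/2")
  }
  if (duration < 10 / band[1]) {
    stop_imcoh("invalid_band",
               "duration too short: need >= 10 cycles of the band low edge")
  }
  n <- round(duration * fs)
  set.seed(seed)
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # fold to [0, fs/2]
  Z[f < band[1] | f > band[2]] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

#' Two envelopes with shared band-limited drive and closed-form coherence
#'
#' Linear common-input model used as an analytic oracle:
#' `x = g1 * c + n1`, `y = g2 * c + n2`, with `c` a shared band-limited drive
#' of variance `drive_var` and `n1`, `n2` independent noises band-limited to
#' the same interval with variance `noise_var`. Because all three spectra are
#' flat over the same band, the magnitude-squared coherence is constant
#' in-band:
#' \deqn{C = (g_1 g_2 \sigma_c^2)^2 / ((g_1^2\sigma_c^2 + \sigma_n^2)
#'           (g_2^2\sigma_c^2 + \sigma_n^2)).}
#'
#' @param g1,g2 nonnegative channel gains on the shared drive.
#' @param drive_var,noise_var variances (>= 0) of drive and per-channel noise.
#' @param band,duration,fs as in [generate_band_limited_noise()].
#' @param seed integer master seed.
#' @return list with `x`, `y`, `coherence_theory`, `fs`, `band`.
#' @export
linear_envelope_pair <- function(g1, g2, drive_var, noise_var, band,
                                 duration, fs, seed) {
  stopifnot(g1 >= 0, g2 >= 0, drive_var >= 0, noise_var >= 0)
  if (g1^2 * drive_var + noise_var == 0 || g2^2 * drive_var + noise_var == 0) {
    stop("each channel needs nonzero total variance")
  }
  set.seed(seed)
  ss <- sample.int(.Machine$integer.max - 1L, 3L)
  nsamp <- round(duration * fs)
  cdrv <- if (drive_var > 0) {
    sqrt(drive_var) * generate_band_limited_noise(band, duration, fs, ss[1])
  } else numeric(nsamp)
  mknoise <- function(s) {
    if (noise_var > 0) {
      sqrt(noise_var) * generate_band_limited_noise(band, duration, fs, s)
    } else numeric(nsamp)
  }
  num <- (g1 * g2 * drive_var)^2
  den <- (g1^2 * drive_var + noise_var) * (g2^2 * drive_var + noise_var)
  list(x = g1 * cdrv + mknoise(ss[2]),
       y = g2 * cdrv + mknoise(ss[3]),
       coherence_theory = if (num == 0) 0 else num / den,
       fs = fs, band = band)
}

#' Synthesize a multichannel common-drive EMG recording
#'
#' Builds the full synthetic acquisition described in [simulation_config()]:
#' per (trial, period) a fresh set of shared band-limited drives per
#' homologous pair, independent carriers and envelope noise per channel, the
#' inter-side delay applied to the shared drive only. Trials are laid out
#' back-to-back; the marker table has `n_trials * length(period_labels)` rows.
#'
#' @param config a [simulation_config()].
#' @return list with `recording` (an [emg_recording]) and `truth`, the ground
#'   truth (coupling, delays, period gains, drive variances, seed, and the
#'   realized clipped-sample fraction).
#' @export
synthesize_recording <- function(config) {
  validate_simulation_config(config)
  fs <- config$sampling_rate
  spt <- round(config$period_duration * fs)        # samples per period
  periods <- config$period_labels
  np <- length(periods)
  trial_len <- np * spt
  total <- config$n_trials * trial_len
  muscles <- config$muscles
  nch <- length(muscles)
  pairs <- unique(pair_of(muscles))
  bands <- names(config$band_defs)

  d_samp <- round(config$delay_ms / 1000 * fs)     # per-pair delay in samples
  pad <- max(abs(d_samp), 0L)

  # deterministic substreams: one seed per generated component
  set.seed(config$seed)
  n_comp <- config$n_trials * np * (length(pairs) * length(bands) + 2L * nch)
  comp_seeds <- sample.int(.Machine$integer.max - 1L, n_comp)
  k <- 0L
  next_seed <- function() { k <<- k + 1L; comp_seeds[k] }

  cp <- config$coupling
  gain_of <- function(pair, period, band) {
    g <- cp$gain[cp$pair == pair & cp$period == period & cp$band == band]
    if (length(g) == 0) 0 else g[1]
  }

  samples <- matrix(0, nch, total, dimnames = list(muscles, NULL))
  n_clipped <- 0
  pad_dur <- (spt + 2 * pad) / fs

  for (tr in seq_len(config$n_trials)) {
    for (pi in seq_len(np)) {
      per <- periods[pi]
      idx <- ((tr - 1) * trial_len + (pi - 1) * spt) + seq_len(spt)
      # shared drives per pair and band, generated with symmetric padding so
      # the delayed side reads a shifted window of the same realization
      drives <- lapply(pairs, function(pr) {
        lapply(bands, function(b) {
          generate_band_limited_noise(config$band_defs[[b]], pad_dur, fs,
                                      next_seed())
        })
      })
      names(drives) <- pairs
      for (m in seq_len(nch)) {
        mus <- muscles[m]
        pr <- pair_of(mus)
        d <- if (side_of(mus) == "r") d_samp[[pr]] else 0L
        acc <- rep(1, spt)
        for (bi in seq_along(bands)) {
          g <- gain_of(pr, per, bands[bi])
          if (g > 0) {
            acc <- acc + g * drives[[pr]][[bi]][(pad + 1 - d):(pad + spt - d)]
          }
        }
        if (config$noise_sd > 0) {
          set.seed(next_seed())
          acc <- acc + stats::rnorm(spt, sd = config$noise_sd)
        } else {
          next_seed()
        }
        n_clipped <- n_clipped + sum(acc < 0)
        env <- config$period_gain[mus, per] * pmax(acc, 0)
        carrier <- generate_band_limited_noise(config$carrier_band,
                                               spt / fs, fs, next_seed())
        samples[m, idx] <- carrier * env
      }
    }
  }

  markers <- data.frame(
    trial = rep(seq_len(config$n_trials), each = np),
    period = rep(periods, config$n_trials),
    onset_sample = as.integer(
      (rep(seq_len(config$n_trials), each = np) - 1) * trial_len +
        (rep(seq_len(np), config$n_trials) - 1) * spt + 1),
    duration_samples = spt,
    stringsAsFactors = FALSE
  )
  rec <- emg_recording(samples, fs = fs, labels = muscles, markers = markers,
                       provenance = list(list(step = "synthesize",
                                              seed = config$seed)))
  truth <- structure(
    list(coupling = config$coupling, delay_ms = as.list(config$delay_ms),
         period_gain = config$period_gain,
         drive_var = stats::setNames(rep(1, length(bands)), bands),
         seed = config$seed,
         clip_fraction = n_clipped / (nch * total / 1L)),
    class = "imc_ground_truth"
  )
  list(recording = rec, truth = truth)
}

#' Ground-truth JSON round trip
#'
#' @param truth the `truth` element of [synthesize_recording()].
#' @param path JSON file path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   returns the ground-truth object.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(coupling = truth$coupling, delay_ms = truth$delay_ms,
              period_gain = list(values = as.vector(truth$period_gain),
                                 muscles = rownames(truth$period_gain),
                                 periods = colnames(truth$period_gain)),
              drive_var = as.list(truth$drive_var), seed = truth$seed,
              clip_fraction = truth$clip_fraction)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pg <- matrix(x$period_gain$values,
               nrow = length(x$period_gain$muscles),
               dimnames = list(x$period_gain$muscles, x$period_gain$periods))
  structure(
    list(coupling = as.data.frame(x$coupling), delay_ms = x$delay_ms,
         period_gain = pg, drive_var = unlist(x$drive_var),
         seed = x$seed, clip_fraction = x$clip_fraction),
    class = "imc_ground_truth"
  )
}
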