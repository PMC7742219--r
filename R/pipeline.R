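#' Pipeline configuration
#'
#' Validated bundle of every tunable in the end-to-end workflow: the
#' simulation block (or input files), spectral-estimation settings, the
#' confidence-limit and IMC-summation variants, and the cohort layout. All
#' settings are serialized into the provenance of every output.
#'
#' @param simulation a [simulation_config()] describing one subject's
#'   recording; per-subject variability is added on top (see `subject_cv`).
#' @param input_paths optional named list with `signal`, `markers` TSV paths
#'   per subject (list of lists) to analyse recorded data instead of
#'   simulating; `NULL` (default) simulates.
#' @param n_subjects cohort size (default 11).
#' @param subject_cv lognormal coefficient of variation applied per subject
#'   to coupling gains and period gains (default 0.2).
#' @param window_ms,overlap Welch settings (defaults 500 ms, 0.75).
#' @param alpha significance level (default 0.05).
#' @param cl_variant confidence-limit formula, see [confidence_limit()].
#' @param imc_variant IMC-area summation variant, see [imc_area()].
#' @param log_offset additive offset before log transform.
#' @param target_fs,hp_cutoff preprocessing settings (Hz).
#' @param seed master seed for the whole run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_paths = NULL,
                            n_subjects = 11, subject_cv = 0.2,
                            window_ms = 500, overlap = 0.75, alpha = 0.05,
                            cl_variant = "rosenberg",
                            imc_variant = "coherence", log_offset = 1e-6,
                            target_fs = 500, hp_cutoff = 20, seed = 1L) {
  cfg <- structure(
    list(simulation = simulation, input_paths = input_paths,
         n_subjects = as.integer(n_subjects), subject_cv = subject_cv,
         window_ms = window_ms, overlap = overlap, alpha = alpha,
         cl_variant = cl_variant, imc_variant = imc_variant,
         log_offset = log_offset, target_fs = target_fs,
         hp_cutoff = hp_cutoff, seed = as.integer(seed)),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (!is.null(cfg$simulation)) validate_simulation_config(cfg$simulation)
  nyq <- cfg$target_fs / 2
  hi <- vapply(cfg$simulation$band_defs, `[`, 0, 2)
  if (any(hi >= nyq)) {
    stop_imcoh("config",
               "band upper edge (%g Hz) at or above the working Nyquist (%g Hz)",
               max(hi), nyq)
  }
  if (cfg$n_subjects < 1) stop_imcoh("config", "n_subjects must be >= 1")
  if (!(cfg$overlap >= 0 && cfg$overlap < 1)) {
    stop_imcoh("config", "overlap must be in [0, 1)")
  }
  if (!(cfg$alpha > 0 && cfg$alpha <= 0.5)) {
    stop_imcoh("config", "alpha must be in (0, 0.5]")
  }
  if (cfg$log_offset <= 0) stop_imcoh("config", "log_offset must be > 0")
  if (cfg$hp_cutoff >= nyq) {
    stop_imcoh("config", "hp_cutoff must be below the working Nyquist")
  }
  invisible(cfg)
}

# per-subject config: fresh seed plus lognormal jitter on coupling gains and
# period gains (between-subject variability)
subject_config <- function(base, subj_seed, coup_jit, gain_jit) {
  cfg <- base
  cfg$seed <- subj_seed
  cfg$coupling$gain <- pmin(1, base$coupling$gain *
                              coup_jit[match(base$coupling$pair,
                                             names(coup_jit))])
  cfg$period_gain <- base$period_gain * gain_jit
  cfg
}

#' Analyse one subject's recording
#'
#' Runs preprocessing, per-period Welch spectra, per-homologous-pair
#' coherence, IMC-area, phase-slope delay, band phase means, normalized PSD
#' and RMS activation for a single recording.
#'
#' @param rec an [emg_recording] with markers.
#' @param cfg a [pipeline_config()].
#' @param subject subject identifier for table rows.
#' @return list of tidy tables: `imc_area`, `delays`, `phase_means`, `rms`,
#'   `spectra`, `psd`.
#' @export
analyse_subject <- function(rec, cfg, subject = 1) {
  pp <- preprocess_recording(rec, target_fs = cfg$target_fs,
                             hp_cutoff = cfg$hp_cutoff)
  periods <- names(pp$epochs$epochs)
  muscles <- pp$epochs$labels
  prs <- unique(pair_of(muscles))
  band_defs <- cfg$simulation$band_defs

  spectra <- list(); imc_rows <- list(); delay_rows <- list()
  phase_rows <- list(); psd_rows <- list()
  for (per in periods) {
    grid <- welch_spectra(pp$epochs, per, window_ms = cfg$window_ms,
                          overlap = cfg$overlap)
    npsd <- normalize_psd(grid)
    psd_rows[[per]] <- data.frame(
      subject = subject, period = per,
      muscle = rep(muscles, each = length(grid$freqs)),
      freq = rep(grid$freqs, length(muscles)),
      psd_norm = as.vector(npsd), stringsAsFactors = FALSE)
    for (pr in prs) {
      chans <- paste0(pr, c("_l", "_r"))
      cs <- coherence(grid, chans, alpha = cfg$alpha,
                      variant = cfg$cl_variant)
      spectra[[paste(pr, per, sep = ".")]] <- cs
      bb <- band_bins(cs$freqs, band_defs)
      for (b in names(band_defs)) {
        d <- estimate_delay(cs, band_defs[[b]], band_label = b)
        delay_rows[[length(delay_rows) + 1L]] <- data.frame(
          subject = subject, pair = pr, period = per, band = b,
          delay_ms = d$delay_ms, slope = d$slope, r_squared = d$r_squared,
          n_bins = d$n_bins, stringsAsFactors = FALSE)
        phase_rows[[length(phase_rows) + 1L]] <- data.frame(
          subject = subject, pair = pr, period = per, band = b,
          phase_mean = Arg(mean(exp(1i * cs$phase[bb[[b]]]))),
          stringsAsFactors = FALSE)
      }
    }
  }
  imc <- imc_area_table(spectra, band_defs, subject = subject,
                        variant = cfg$imc_variant)
  rms <- rms_activation(pp$filtered)
  rms$subject <- subject
  sp_tidy <- do.call(rbind, lapply(spectra, function(cs) {
    data.frame(subject = subject, pair = pair_of(cs$pair[1]),
               period = cs$period, freq = cs$freqs,
               coherence = cs$coherence, phase = cs$phase, cl = cs$cl,
               stringsAsFactors = FALSE)
  }))
  rownames(sp_tidy) <- NULL
  list(imc_area = imc, delays = do.call(rbind, delay_rows),
       phase_means = do.call(rbind, phase_rows), rms = rms,
       spectra = sp_tidy, psd = do.call(rbind, psd_rows))
}

#' Run the full IMC workflow
#'
#' Simulates (or loads) a cohort of recordings, analyses each subject
#' independently, pools the per-subject tables, and runs the statistical
#' layer: per band a two-way repeated-measures ANOVA on log IMC area
#' (factors muscle pair and movement period) with Holm-adjusted post hocs
#' for significant effects, a two-way rmANOVA on phase-slope delays, one-way
#' rmANOVAs on RMS activation (factors MUSCLE and PERIOD), and one-sample t
#' tests of band phase means against zero.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory; when given, all result tables are
#'   written as TSV plus a provenance JSON.
#' @return list of class `imc_pipeline_result` with elements `tables`
#'   (imc_area, rms, delays, phase_means, spectra, psd), `anova`, `posthoc`,
#'   `phase_tests`, `config`, `subject_seeds`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  validate_pipeline_config(cfg)
  set.seed(cfg$seed)
  ns <- cfg$n_subjects
  subj_seeds <- sample.int(.Machine$integer.max - 1L, ns)
  prs <- unique(pair_of(cfg$simulation$muscles))
  coup_jit <- matrix(exp(stats::rnorm(ns * length(prs), 0, cfg$subject_cv)),
                     ns, dimnames = list(NULL, prs))
  gain_jit <- exp(stats::rnorm(ns, 0, cfg$subject_cv))

  per_subject <- lapply(seq_len(ns), function(s) {
    rec <- if (is.null(cfg$input_paths)) {
      sc <- subject_config(cfg$simulation, subj_seeds[s], coup_jit[s, ],
                           gain_jit[s])
      synthesize_recording(sc)$recording
    } else {
      read_recording_tsv(cfg$input_paths[[s]]$signal,
                         cfg$input_paths[[s]]$markers)
    }
    analyse_subject(rec, cfg, subject = s)
  })
  tables <- lapply(c("imc_area", "rms", "delays", "phase_means", "spectra",
                     "psd"),
                   function(nm) {
                     out <- do.call(rbind, lapply(per_subject, `[[`, nm))
                     rownames(out) <- NULL
                     out
                   })
  names(tables) <- c("imc_area", "rms", "delays", "phase_means", "spectra",
                     "psd")
  tables$imc_area <- log_transform_table(tables$imc_area, cfg$log_offset)

  bands <- names(cfg$simulation$band_defs)
  anova <- list(); posthoc <- list()
  for (b in bands) {
    sub <- tables$imc_area[tables$imc_area$band == b, ]
    an <- rm_anova(sub, "log_imc_area", c("pair", "period"))
    anova[[paste0("imc_", b)]] <- an
    ph <- list()
    if (an$p[an$effect == "pair"] < cfg$alpha) {
      ph$pair <- posthoc_pairwise(sub, "log_imc_area", "pair")
    }
    if (an$p[an$effect == "period"] < cfg$alpha) {
      ph$period <- posthoc_pairwise(sub, "log_imc_area", "period")
    }
    if (an$p[an$effect == "pair:period"] < cfg$alpha) {
      ph$interaction <- posthoc_pairwise(sub, "log_imc_area", "pair",
                                         by = "period")
    }
    posthoc[[paste0("imc_", b)]] <- ph
    dsub <- tables$delays[tables$delays$band == b, ]
    anova[[paste0("delay_", b)]] <- rm_anova(dsub, "delay_ms",
                                             c("pair", "period"))
  }
  # one-way rmANOVAs on RMS activation: MUSCLE (periods averaged), PERIOD
  rms_m <- stats::aggregate(rms_mean ~ subject + muscle, tables$rms, mean)
  rms_p <- stats::aggregate(rms_mean ~ subject + period, tables$rms, mean)
  anova$rms_muscle <- rm_anova(rms_m, "rms_mean", "muscle")
  anova$rms_period <- rm_anova(rms_p, "rms_mean", "period")
  if (anova$rms_muscle$p[1] < cfg$alpha) {
    posthoc$rms_muscle <- posthoc_pairwise(rms_m, "rms_mean", "muscle")
  }
  if (anova$rms_period$p[1] < cfg$alpha) {
    posthoc$rms_period <- posthoc_pairwise(rms_p, "rms_mean", "period")
  }
  # one-sample t tests of band phase means against zero
  pm <- tables$phase_means
  keys <- unique(pm[c("pair", "period", "band")])
  phase_tests <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    v <- pm$phase_mean[pm$pair == keys$pair[i] &
                         pm$period == keys$period[i] &
                         pm$band == keys$band[i]]
    tt <- one_sample_t(v, mu = 0)
    cbind(keys[i, , drop = FALSE],
          data.frame(t = tt$t, df = tt$df, p = tt$p, mean_phase = tt$mean))
  }))
  phase_tests$p_adjusted <- holm_adjust(phase_tests$p)
  rownames(phase_tests) <- NULL

  res <- structure(
    list(tables = tables, anova = anova, posthoc = posthoc,
         phase_tests = phase_tests, config = cfg,
         subject_seeds = subj_seeds),
    class = "imc_pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_results(res, out_dir)
  res
}

#' Write pipeline result tables as TSV
#'
#' @param res an `imc_pipeline_result`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, nm) {
    data.table::fwrite(df, file.path(out_dir, paste0(nm, ".tsv")), sep = "\t")
  }
  for (nm in names(res$tables)) wt(res$tables[[nm]], nm)
  an <- do.call(rbind, lapply(names(res$anova), function(nm) {
    cbind(data.frame(analysis = nm), res$anova[[nm]])
  }))
  wt(an, "anova")
  ph <- do.call(rbind, lapply(names(res$posthoc), function(nm) {
    fams <- res$posthoc[[nm]]
    if (is.data.frame(fams)) fams <- list(all = fams)
    do.call(rbind, lapply(names(fams), function(f) {
      df <- fams[[f]]
      if (!"by" %in% names(df)) df$by <- NA_character_
      cbind(data.frame(analysis = nm, family = f),
            df[c("by", "comparison", "t", "df", "p_raw", "p_adjusted",
                 "significant")])
    }))
  }))
  if (!is.null(ph) && nrow(ph)) wt(ph, "posthoc")
  wt(res$phase_tests, "phase_tests")
  prov <- res$config
  prov$simulation$period_gain <- list(
    values = as.vector(prov$simulation$period_gain),
    muscles = rownames(prov$simulation$period_gain),
    periods = colnames(prov$simulation$period_gain))
  jsonlite::write_json(
    list(config = prov, subject_seeds = res$subject_seeds,
         r_version = as.character(getRversion())),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(out_dir)
}

#' Summarize a pipeline run
#'
#' Human-readable digest of the statistical layer: which effects reached
#' significance per band, the post hoc contrasts, and amplitude results.
#' Optionally writes per-pair coherence spectra (with the confidence limit)
#' and IMC-area summary figures as PNG.
#'
#' @param res an `imc_pipeline_result`.
#' @param plot_dir optional directory for figures.
#' @return character vector of summary lines (also printed), invisibly.
#' @export
report <- function(res, plot_dir = NULL) {
  needed <- c("tables", "anova", "posthoc", "phase_tests", "config")
  miss <- needed[!vapply(needed, function(nm) !is.null(res[[nm]]), TRUE)]
  if (!inherits(res, "imc_pipeline_result") || length(miss)) {
    stop_imcoh("incomplete_bundle", "result bundle incomplete; missing: %s",
               paste(if (length(miss)) miss else "everything",
                     collapse = ", "))
  }
  alpha <- res$config$alpha
  lines <- c(sprintf("IMC pipeline summary (%d subjects, alpha = %g)",
                     res$config$n_subjects, alpha))
  for (nm in names(res$anova)) {
    an <- res$anova[[nm]]
    sig <- an[an$p < alpha, , drop = FALSE]
    lines <- c(lines, sprintf("[%s] %s", nm, if (nrow(sig) == 0) {
      "no significant effects"
    } else {
      paste(sprintf("%s: F(%d,%d) = %.2f, p = %.4g", sig$effect, sig$df1,
                    sig$df2, sig$F, sig$p), collapse = "; ")
    }))
  }
  for (nm in names(res$posthoc)) {
    fams <- res$posthoc[[nm]]
    if (is.data.frame(fams)) fams <- list(all = fams)
    for (f in names(fams)) {
      sig <- fams[[f]][fams[[f]]$significant, , drop = FALSE]
      if (nrow(sig)) {
        lines <- c(lines, sprintf(
          "[%s/%s post hoc] %s", nm, f,
          paste(sprintf("%s%s (p_holm = %.4g)",
                        if (!is.null(sig$by)) paste0(sig$by, ": ") else "",
                        sig$comparison, sig$p_adjusted), collapse = "; ")))
      }
    }
  }
  n_phase <- sum(res$phase_tests$p_adjusted < alpha)
  lines <- c(lines, sprintf(
    "phase angles: %s differ from zero (Holm-adjusted)",
    if (n_phase == 0) "none" else sprintf("%d of %d", n_phase,
                                          nrow(res$phase_tests))))
  if (!is.null(plot_dir)) plot_pipeline_results(res, plot_dir)
  cat(lines, sep = "\n")
  invisible(lines)
}

# coherence-spectrum grid and IMC-area summary figures (base graphics)
plot_pipeline_results <- function(res, plot_dir) {
  dir.create(plot_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- res$tables$spectra
  prs <- unique(sp$pair)
  pers <- unique(sp$period)
  grDevices::png(file.path(plot_dir, "coherence_spectra.png"),
                 width = 300 * length(prs), height = 260 * length(pers))
  graphics::par(mfrow = c(length(pers), length(prs)),
                mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  for (per in pers) {
    for (pr in prs) {
      sub <- sp[sp$pair == pr & sp$period == per, ]
      avg <- stats::aggregate(coherence ~ freq, sub, mean)
      graphics::plot(avg$freq, avg$coherence, type = "l", lwd = 2,
                     xlim = c(0, 60), ylim = c(0, max(avg$coherence) * 1.2),
                     xlab = "frequency (Hz)", ylab = "coherence",
                     main = sprintf("%s (%s)", pr, per))
      graphics::abline(h = mean(sub$cl), lty = 2, col = "darkgreen")
    }
  }
  grDevices::dev.off()
  imc <- res$tables$imc_area
  grDevices::png(file.path(plot_dir, "imc_area.png"), width = 900,
                 height = 320)
  graphics::par(mfrow = c(1, length(unique(imc$band))),
                mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  for (b in unique(imc$band)) {
    sub <- imc[imc$band == b, ]
    graphics::boxplot(log_imc_area ~ period, sub, xlab = "period",
                      ylab = "log IMC area", main = b)
  }
  grDevices::dev.off()
  invisible(plot_dir)
}
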