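test_that("band assignment puts shared edge bins in the upper band only", {
  freqs <- seq(0, 250, by = 2)
  defs <- list(alpha = c(8, 12), beta = c(13, 30), gamma = c(30, 44))
  bb <- band_bins(freqs, defs)
  expect_equal(freqs[bb$alpha], c(8, 10, 12))
  expect_equal(freqs[bb$beta], seq(14, 28, by = 2))
  expect_equal(freqs[bb$gamma], seq(30, 44, by = 2))
  expect_equal(length(intersect(bb$beta, bb$gamma)), 0)
})

test_that("IMC area sums only significant bins", {
  freqs <- c(14, 16, 18)
  cs <- toy_coherence_spectrum(freqs, c(0.10, 0.40, 0.60), cl = 0.30)
  a <- imc_area(cs, c(13, 30))
  expect_equal(a$imc_area, 1.00)
  expect_equal(a$n_sig_bins, 2)

  below <- toy_coherence_spectrum(freqs, c(0.1, 0.2, 0.29), cl = 0.30)
  expect_equal(imc_area(below, c(13, 30)),
               list(imc_area = 0, n_sig_bins = 0))

  # the upper bound (all bins at 1) is attained for self-coherence
  freqs2 <- seq(0, 250, by = 2)
  self <- toy_coherence_spectrum(freqs2, rep(1, length(freqs2)), cl = 0.3)
  a2 <- imc_area(self, c(8, 12))
  expect_equal(a2$imc_area, 3)
  expect_equal(a2$n_sig_bins, 3)

  ex <- imc_area(cs, c(13, 30), variant = "excess")
  expect_equal(ex$imc_area, (0.4 - 0.3) + (0.6 - 0.3))
})

test_that("log transform floors empty cells and preserves order", {
  tab <- data.frame(subject = 1, pair = "VL", period = "ISO",
                    band = c("alpha", "beta", "gamma"),
                    imc_area = c(0, 1 - 1e-6, 2.5), n_sig_bins = c(0, 3, 5))
  out <- log_transform_table(tab)
  expect_equal(out$log_imc_area[1], log(1e-6))
  expect_equal(out$log_imc_area[2], 0, tolerance = 1e-9)
  expect_true(all(diff(out$log_imc_area) > 0))
  expect_equal(attr(out, "log_offset"), 1e-6)

  tab$imc_area[1] <- -1
  expect_error(log_transform_table(tab), class = "imcoh_corrupted_table")
})

test_that("RMS activation ratios normalize per muscle and window correctly", {
  fs <- 500
  mk <- data.frame(trial = rep(1:2, each = 2),
                   period = rep(c("ECC", "ISO"), 2),
                   onset_sample = c(1, 2501, 5001, 7501),
                   duration_samples = 2500)
  tt <- (0:(4 * 2500 - 1)) / fs
  # ch1: constant 2 in ECC, constant 4 in ISO; ch2: 50-Hz sinusoid whose
  # amplitude doubles in ISO (window RMS = A/sqrt(2) cancels in the ratio)
  per <- rep(rep(c("ECC", "ISO"), 2), each = 2500)
  ch1 <- ifelse(per == "ISO", 4, 2)
  ch2 <- ifelse(per == "ISO", 2, 1) * sin(2 * pi * 50 * tt)
  rec <- emg_recording(rbind(m1 = ch1, m2 = ch2), fs = fs, markers = mk)
  out <- rms_activation(rec)
  expect_equal(attr(out, "window_samples"), 25)
  expect_equal(unname(attr(out, "n_windows")), c(200, 200))  # 100 per trial
  expect_equal(out$rms_mean[out$muscle == "m1" & out$period == "ISO"], 1)
  expect_equal(out$rms_mean[out$muscle == "m1" & out$period == "ECC"], 0.5)
  expect_equal(out$rms_mean[out$muscle == "m2" & out$period == "ECC"], 0.5,
               tolerance = 1e-6)

  rec0 <- emg_recording(rbind(m1 = ch1, m2 = 0 * ch2), fs = fs, markers = mk)
  expect_error(rms_activation(rec0), class = "imcoh_undefined_normalization")
})

test_that("normalized PSD sums to one, is scale-free and splits tone power", {
  fs <- 500
  tt <- (0:(500 * 60 - 1)) / fs
  x <- sqrt(3) * sin(2 * pi * 20 * tt) + sin(2 * pi + 2 * pi * 40 * tt)
  ep <- as_epochs(a = x, b = 10 * x, fs = fs)
  g <- welch_spectra(ep, "ALL")
  np <- normalize_psd(g)
  expect_equal(colSums(np), c(a = 1, b = 1), tolerance = 1e-12)
  expect_equal(np[, "a"], np[, "b"], tolerance = 1e-12)
  m20 <- sum(np[abs(g$freqs - 20) <= 4, "a"])
  m40 <- sum(np[abs(g$freqs - 40) <= 4, "a"])
  expect_equal(m20 / (m20 + m40), 0.75, tolerance = 0.02)

  ep0 <- as_epochs(a = rep(0, 1000), b = rnorm(1000), fs = fs)
  expect_error(normalize_psd(welch_spectra(ep0, "ALL")),
               class = "imcoh_degenerate_spectrum")
})

test_that("raising the isometric period gain moves RMS but not IMC area", {
  mkcfg <- function(iso_gain, seed) {
    coupling <- expand.grid(pair = "VL", period = c("ECC", "ISO"),
                            band = c("alpha", "beta", "gamma"),
                            stringsAsFactors = FALSE)
    coupling$gain <- ifelse(coupling$band == "beta", 0.4, 0)
    simulation_config(
      sampling_rate = 1000, n_trials = 6, period_labels = c("ECC", "ISO"),
      muscles = c("VL_l", "VL_r"), coupling = coupling, delay_ms = c(VL = 0),
      period_gain = matrix(c(0.8, 0.8, iso_gain, iso_gain), 2, 2,
                           dimnames = list(c("VL_l", "VL_r"),
                                           c("ECC", "ISO"))),
      noise_sd = 0.2, seed = seed)
  }
  n <- 12
  area <- matrix(0, n, 2)
  ecc_ratio <- matrix(0, n, 2)
  for (s in seq_len(n)) {
    for (arm in 1:2) {
      cfg <- mkcfg(c(1.2, 3.6)[arm], seed = 500 + s)
      pp <- preprocess_recording(synthesize_recording(cfg)$recording)
      cs <- coherence(welch_spectra(pp$epochs, "ISO"), c("VL_l", "VL_r"))
      area[s, arm] <- imc_area(cs, c(13, 30))$imc_area
      rms <- rms_activation(pp$filtered)
      ecc_ratio[s, arm] <- mean(rms$rms_mean[rms$period == "ECC"])
    }
  }
  # amplitude changed threefold: ECC activation ratios drop accordingly
  expect_true(all(ecc_ratio[, 2] < 0.5 * ecc_ratio[, 1]))
  # ... while band-summed coherence is statistically unchanged
  expect_gt(t.test(area[, 1], area[, 2], paired = TRUE)$p.value, 0.05)
  expect_lt(mean(abs(area[, 2] - area[, 1])) / mean(area[, 1]), 1e-3)
})

test_that("IMC area is invariant to channel amplitude scaling", {
  set.seed(10)
  ep <- noise_epochs(6, 2500, nch = 2, labels = c("VL_l", "VL_r"))
  shared <- lapply(ep$epochs$ISO, function(m) {
    s <- rnorm(ncol(m)); m + rbind(s, s)
  })
  ep$epochs$ISO <- shared
  defs <- list(alpha = c(8, 12), beta = c(13, 30), gamma = c(30, 44))
  tab1 <- imc_area_table(list(coherence(welch_spectra(ep, "ISO"),
                                        c("VL_l", "VL_r"))), defs)
  ep2 <- ep
  ep2$epochs$ISO <- lapply(ep$epochs$ISO, function(m) { m[1, ] <- 37 * m[1, ]; m })
  tab2 <- imc_area_table(list(coherence(welch_spectra(ep2, "ISO"),
                                        c("VL_l", "VL_r"))), defs)
  expect_equal(tab1$n_sig_bins, tab2$n_sig_bins)
  expect_lt(max(abs(tab1$imc_area - tab2$imc_area)), 1e-9)
})
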