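test_that("band-limited noise is deterministic, standardized and in-band", {
  x1 <- generate_band_limited_noise(c(13, 30), 300, 500, seed = 7)
  x2 <- generate_band_limited_noise(c(13, 30), 300, 500, seed = 7)
  expect_identical(x1, x2)

  expect_equal(mean(x1), 0, tolerance = 1e-12)
  expect_lt(abs(var(x1) - 1), 0.02)

  # in-band power fraction from the raw periodogram
  n <- length(x1)
  p <- Mod(fft(x1))^2 / n
  f <- pmin((seq_len(n) - 1) * 500 / n, 500 - (seq_len(n) - 1) * 500 / n)
  frac <- sum(p[f >= 13 & f <= 30]) / sum(p)
  expect_gte(frac, 0.95)

  expect_error(generate_band_limited_noise(c(100, 300), 10, 500, 1),
               class = "imcoh_invalid_band")
  expect_error(generate_band_limited_noise(c(8, 12), 0.5, 500, 1),
               class = "imcoh_invalid_band")
})

test_that("linear common-input pair matches its closed-form coherence", {
  # no shared input
  z <- linear_envelope_pair(0, 1, 1, 1, c(13, 30), 20, 500, 1)
  expect_identical(z$coherence_theory, 0)
  # equal drive and noise spectra: ((1*1*1)^2)/((1+1)(1+1)) = 1/4
  q <- linear_envelope_pair(1, 1, 1, 1, c(13, 30), 20, 500, 1)
  expect_equal(q$coherence_theory, 0.25)
  # noise-free channels are identical up to scale
  p <- linear_envelope_pair(2, 0.5, 1, 0, c(13, 30), 20, 500, 1)
  expect_equal(p$coherence_theory, 1)
  expect_equal(p$x / 2, p$y / 0.5, tolerance = 1e-12)
})

test_that("synthetic recordings are reproducible and structurally correct", {
  cfg <- simulation_config(sampling_rate = 1000, n_trials = 3, seed = 11)
  a <- synthesize_recording(cfg)
  b <- synthesize_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)

  rec <- a$recording
  expect_equal(nrow(rec$samples), 8)
  expect_equal(nrow(rec$markers), 3 * 3)
  expect_equal(rec$fs, 1000)
  # trials laid out back-to-back: one repetition spans 3 periods x 5 s
  on <- rec$markers$onset_sample[rec$markers$period == "ECC"]
  expect_equal(diff(on), rep(15 * 1000, 2))
  expect_lt(a$truth$clip_fraction, 0.01)
})

test_that("invalid simulation configs fail naming the offending field", {
  expect_error(simulation_config(sampling_rate = 300),
               "sampling_rate", class = "imcoh_config")
  expect_error(simulation_config(band_defs = list(alpha = c(8, 14),
                                                  beta = c(13, 30))),
               "band_defs", class = "imcoh_config")
  cfg <- simulation_config(sampling_rate = 1000, n_trials = 2)
  cfg$coupling$gain[1] <- 1.5
  expect_error(synthesize_recording(cfg), "coupling",
               class = "imcoh_config")
  expect_error(simulation_config(delay_ms = c(VL = 6000, VM = 0, TA = 0,
                                              ES = 0)),
               "delay_ms", class = "imcoh_config")
})

test_that("ground truth round-trips through JSON unchanged", {
  cfg <- simulation_config(sampling_rate = 1000, n_trials = 2,
                           delay_ms = c(VL = 4, VM = 0, TA = -2, ES = 0),
                           seed = 3)
  tr <- synthesize_recording(cfg)$truth
  path <- tempfile(fileext = ".json")
  write_ground_truth(tr, path)
  back <- read_ground_truth(path)
  expect_equal(back$coupling$gain, tr$coupling$gain)
  expect_equal(back$delay_ms$VL, 4)
  expect_equal(back$period_gain, tr$period_gain)
  expect_equal(back$seed, tr$seed)
})

test_that("recording TSV round trip preserves samples, rate and markers", {
  cfg <- simulation_config(sampling_rate = 1000, n_trials = 2, seed = 5)
  rec <- synthesize_recording(cfg)$recording
  sp <- tempfile(fileext = ".tsv"); mp <- tempfile(fileext = ".tsv")
  write_recording_tsv(rec, sp, mp)
  back <- read_recording_tsv(sp, mp)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$labels, rec$labels)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_equal(back$markers$onset_sample, rec$markers$onset_sample)
})
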