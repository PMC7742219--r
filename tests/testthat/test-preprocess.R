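make_rec <- function(x, fs, markers = NULL) {
  emg_recording(matrix(x, nrow = 1, dimnames = list("ch1", NULL)), fs = fs,
                markers = markers)
}

test_that("decimation preserves DC and passband tones, rescales markers", {
  fs <- 3000
  mk <- data.frame(trial = 1, period = "ECC", onset_sample = 3001,
                   duration_samples = 15000)
  rec <- make_rec(rep(3, fs * 10), fs, mk)
  dec <- decimate_recording(rec)
  expect_equal(dec$fs, 500)
  expect_equal(ncol(dec$samples), fs * 10 / 6)
  mid <- dec$samples[1, 500:4500]
  expect_lt(max(abs(mid - 3)), 1e-3)
  expect_equal(dec$markers$onset_sample, 501)
  expect_equal(dec$markers$duration_samples, 2500)

  tt <- (0:(fs * 10 - 1)) / fs
  tone <- decimate_recording(make_rec(sin(2 * pi * 10 * tt), fs))
  amp <- max(abs(tone$samples[1, 500:4500]))
  expect_lt(abs(amp - 1), 0.01)

  expect_error(decimate_recording(make_rec(rnorm(1000), 1100)),
               class = "imcoh_unsupported_rate")
})

test_that("high-pass rejects DC and slow drift but passes 50 Hz", {
  fs <- 500
  set.seed(1)
  x <- rnorm(fs * 20) + 5
  hp <- highpass_recording(make_rec(x, fs))
  expect_lt(abs(mean(hp$samples)), 1e-6 * sd(x))

  tt <- (0:(fs * 20 - 1)) / fs
  h50 <- highpass_recording(make_rec(sin(2 * pi * 50 * tt), fs))
  # amplitude via RMS over an integer number of cycles (the 10-sample cycle
  # never lands on the sine peak)
  amp50 <- sqrt(2 * mean(h50$samples[1, 1001:9000]^2))
  expect_lt(abs(amp50 - 1), 0.02)
  h2 <- highpass_recording(make_rec(sin(2 * pi * 2 * tt), fs))
  expect_lt(sqrt(2 * mean(h2$samples[1, 1001:9000]^2)), 0.01)

  expect_error(highpass_recording(make_rec(x, fs), cutoff = 300),
               class = "imcoh_invalid_cutoff")
})

test_that("zero-phase filtering introduces no group delay", {
  fs <- 500
  tt <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * 40 * tt) * exp(-((tt - 5) / 1)^2)  # localized burst
  y <- highpass_recording(make_rec(x, fs))$samples[1, ]
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("Hilbert envelope demodulates tones and AM signals", {
  fs <- 500
  tt <- (0:(fs * 10 - 1)) / fs
  env <- hilbert_envelope(make_rec(sin(2 * pi * 30 * tt), fs))
  core <- env$samples[1, 51:(length(tt) - 50)]  # skip 100 ms edges
  expect_lt(max(abs(core - 1)), 0.01)
  expect_true(all(env$samples >= 0))

  am <- (1 + 0.5 * cos(2 * pi * 2 * tt)) * cos(2 * pi * 50 * tt)
  got <- hilbert_envelope(make_rec(am, fs))$samples[1, ]
  want <- 1 + 0.5 * cos(2 * pi * 2 * tt)
  sel <- 51:(length(tt) - 50)
  expect_lt(sqrt(mean((got[sel] - want[sel])^2)) / sqrt(mean(want[sel]^2)),
            0.02)

  z <- hilbert_envelope(make_rec(rep(0, 1000), fs))
  expect_true(all(z$samples == 0))
})

test_that("epoching yields the marked trial structure or fails loudly", {
  fs <- 500
  n_tr <- 4
  per <- c("ECC", "ISO", "CON")
  mk <- data.frame(
    trial = rep(seq_len(n_tr), each = 3), period = rep(per, n_tr),
    onset_sample = seq(1, by = 2500, length.out = 12),
    duration_samples = 2500)
  rec <- emg_recording(matrix(abs(rnorm(2 * 12 * 2500)), 2), fs = fs,
                       markers = mk)
  ep <- epoch_envelopes(rec)
  expect_named(ep$epochs, per)
  expect_length(ep$epochs$ECC, n_tr)
  expect_equal(ncol(ep$epochs$ISO[[2]]), 2500)

  rec$markers <- NULL
  expect_error(epoch_envelopes(rec), class = "imcoh_empty_markers")
  mk2 <- mk; mk2$onset_sample[12] <- 1e6
  expect_error(emg_recording(matrix(0, 2, 12 * 2500), fs = fs, markers = mk2),
               class = "imcoh_marker_range")
  mk3 <- mk; mk3$duration_samples[2] <- 2000
  rec3 <- emg_recording(rec$samples, fs = fs, markers = mk3)
  expect_error(epoch_envelopes(rec3), class = "imcoh_inconsistent_epoch")
})

test_that("the preprocessing chain is reproducible and records provenance", {
  cfg <- simulation_config(sampling_rate = 1000, n_trials = 2, seed = 9)
  rec <- synthesize_recording(cfg)$recording
  a <- preprocess_recording(rec)
  b <- preprocess_recording(rec)
  expect_identical(a$epochs$epochs, b$epochs$epochs)
  steps <- vapply(a$epochs$provenance, `[[`, "", "step")
  expect_equal(steps, c("synthesize", "decimate", "highpass",
                        "hilbert_envelope", "epoch"))
  expect_true(all(unlist(a$epochs$epochs) >= 0))
  expect_equal(a$epochs$fs, 500)
})
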