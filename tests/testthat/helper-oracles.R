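# Independent oracles used across the suite. These deliberately re-derive
# quantities with the most direct computation available (raw DFT products,
# explicit sum-of-squares decompositions) and share no code with the package
# estimators they check.

# Magnitude-squared coherence by direct averaging of raw windowed DFT
# products over segments of one continuous record.
oracle_coherence <- function(x, y, L, step) {
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L))
  starts <- seq(1, length(x) - L + 1, by = step)
  Sxx <- Syy <- 0
  Sxy <- 0 + 0i
  for (s in starts) {
    xs <- x[s:(s + L - 1)]
    ys <- y[s:(s + L - 1)]
    X <- fft((xs - mean(xs)) * w)
    Y <- fft((ys - mean(ys)) * w)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  (Mod(Sxy)^2 / (Sxx * Syy))[1:(L %/% 2 + 1)]
}

# Classical balanced two-way within-subject ANOVA via the explicit
# sum-of-squares decomposition on a long-format table.
oracle_rm_anova2 <- function(tab, dv, fA, fB, subject = "subject") {
  y <- tab[[dv]]
  A <- factor(tab[[fA]]); B <- factor(tab[[fB]]); S <- factor(tab[[subject]])
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  g <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mS <- tapply(y, S, mean)
  mAB <- tapply(y, list(A, B), mean)
  mAS <- tapply(y, list(A, S), mean)
  mBS <- tapply(y, list(B, S), mean)
  ss_A <- n * b * sum((mA - g)^2)
  ss_B <- n * a * sum((mB - g)^2)
  ss_AB <- n * sum((mAB - outer(mA, rep(1, b)) -
                      outer(rep(1, a), mB) + g)^2)
  ss_AS <- b * sum((mAS - outer(mA, rep(1, n)) -
                      outer(rep(1, a), mS) + g)^2)
  ss_BS <- a * sum((mBS - outer(mB, rep(1, n)) -
                      outer(rep(1, b), mS) + g)^2)
  resid <- y
  for (i in seq_along(y)) {
    resid[i] <- y[i] - mAB[A[i], B[i]] - mAS[A[i], S[i]] - mBS[B[i], S[i]] +
      mA[A[i]] + mB[B[i]] + mS[S[i]] - g
  }
  ss_ABS <- sum(resid^2)
  f <- function(ss, df, ss_e, df_e) (ss / df) / (ss_e / df_e)
  data.frame(
    effect = c(fA, fB, paste0(fA, ":", fB)),
    df1 = c(a - 1, b - 1, (a - 1) * (b - 1)),
    df2 = c((a - 1) * (n - 1), (b - 1) * (n - 1), (a - 1) * (b - 1) * (n - 1)),
    F = c(f(ss_A, a - 1, ss_AS, (a - 1) * (n - 1)),
          f(ss_B, b - 1, ss_BS, (b - 1) * (n - 1)),
          f(ss_AB, (a - 1) * (b - 1), ss_ABS, (a - 1) * (b - 1) * (n - 1))),
    stringsAsFactors = FALSE
  )
}

# white-noise envelope epochs: `n_epochs` trials of `len` samples, `nch`
# independent channels, as an epoched_envelopes container
noise_epochs <- function(n_epochs, len, nch = 2, fs = 500, period = "ISO",
                         labels = paste0("ch", seq_len(nch))) {
  eps <- lapply(seq_len(n_epochs), function(i) {
    matrix(rnorm(nch * len), nch, len, dimnames = list(labels, NULL))
  })
  structure(list(epochs = setNames(list(eps), period), fs = fs,
                 labels = labels, provenance = list()),
            class = "epoched_envelopes")
}

# hand-built coherence_spectrum for table-level unit tests
toy_coherence_spectrum <- function(freqs, coh, cl, phase = rep(0, length(freqs)),
                                   pair = c("VL_l", "VL_r"), period = "ISO") {
  structure(list(freqs = freqs, coherence = coh, phase = phase, cl = cl,
                 alpha = 0.05, n_effective = 100, n_disjoint = 100,
                 n_segments = 100, pair = pair, period = period, fs = 500,
                 window_ms = 500),
            class = "coherence_spectrum")
}

# small two-channel homologous simulation used by several recovery tests
small_pair_config <- function(gain_beta, n_trials = 8, fs = 1000,
                              noise_sd = 0.2, delay_ms = 0, seed = 1) {
  coupling <- expand.grid(pair = "VL", period = "ISO",
                          band = c("alpha", "beta", "gamma"),
                          stringsAsFactors = FALSE)
  coupling$gain <- ifelse(coupling$band == "beta", gain_beta, 0)
  simulation_config(
    sampling_rate = fs, n_trials = n_trials, period_labels = "ISO",
    period_duration = 5, muscles = c("VL_l", "VL_r"),
    coupling = coupling, delay_ms = c(VL = delay_ms),
    period_gain = matrix(1, 2, 1, dimnames = list(c("VL_l", "VL_r"), "ISO")),
    noise_sd = noise_sd, seed = seed)
}
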