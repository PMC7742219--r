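# imcoh — intermuscular coherence analysis of multichannel surface EMG

`imcoh` quantifies **common oscillatory drive** to pairs of muscles from
multichannel surface electromyography (EMG). When two motoneuron pools
receive shared synaptic input, their EMG envelopes become correlated at the
input's frequencies; the frequency-resolved strength of that correlation is
the **intermuscular coherence** (IMC). The package implements the complete
workflow used in bilateral motor-control studies — e.g. comparing homologous
left/right muscle pairs (vastus lateralis VL, vastus medialis VM, tibialis
anterior TA, erector spinae ES) across movement periods of a compound
movement (eccentric ECC, isometric ISO, concentric CON) — together with a
synthetic common-drive EMG generator so that every stage of the chain can be
validated against a known ground truth.

## The statistic at the core

For two channels `x`, `y`, Welch auto-/cross-spectra over Hann-windowed
segments of the concatenated trial envelopes give the magnitude-squared
coherence

```
C_xy(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f)),           0 <= C_xy(f) <= 1
```

with phase `phi(f) = arg S_xy(f)`. A coherence value is significant at level
`alpha` when it exceeds the Rosenberg-type confidence limit

```
CL = 1 - alpha^(1/(N - 1))
```

where `N` is the number of independent segments; with overlapping segments
`N` is replaced by an effective count derived from the squared window
autocorrelations (for a Hann window at 75% overlap the count grows by a
factor of about 1.94 over the disjoint count — validated here by Monte-Carlo
type-I calibration). Downstream summaries:

* **IMC area** — the sum of significant coherence values over a frequency
  band (alpha 8–12 Hz, beta 13–30 Hz, gamma 30–44 Hz), log-transformed for
  inference; preferred to peak coherence.
* **Phase-slope delay** — the least-squares slope of the unwrapped
  cross-spectral phase over a band, divided by 2π, giving the inter-muscle
  lag in ms.
* **Activation ratio** — 50-ms windowed RMS amplitude normalized to each
  muscle's maximum window, to show that amplitude differences do not drive
  coherence differences.
* **Inference** — two-way repeated-measures ANOVAs (muscle pair × movement
  period) on log IMC area and delays, one-way rmANOVAs on activation, Holm
  (step-down Bonferroni) post hocs, one-sample t tests of phase angles.

## Worked example

```r
library(imcoh)

cfg <- simulation_config(sampling_rate = 1000, n_trials = 4, seed = 1)
rec <- synthesize_recording(cfg)$recording
pp  <- preprocess_recording(rec)    # decimate -> 20 Hz high-pass -> envelope -> epoch
g   <- welch_spectra(pp$epochs, "ECC")
cs  <- coherence(g, c("ES_l", "ES_r"))
cs
#> <coherence_spectrum> ES_l - ES_r (period ECC)
#>   126 bins, CL(alpha=0.05) = 0.03847, 77.4 effective segments
#>   peak coherence 0.509 at 10 Hz
imc_area(cs, c(13, 30))
#> $imc_area
#> [1] 2.033348
#> $n_sig_bins
#> [1] 8
```

The erector spinae pair shares band-limited drive by construction, so its
coherence peaks far above the confidence limit (0.038 for 77 effective
segments); summing the 8 significant beta-band bins gives an IMC area of
2.03. A full cohort analysis is one call:

```r
res <- run_pipeline(pipeline_config(n_subjects = 11, seed = 1), out_dir = "results/cohort")
report(res)
```

## Analysis workflow

The `analysis/` scripts run the study-scale workflow end to end and write
all tables under `results/`:

| script | what it does |
| --- | --- |
| `analysis/01_simulate.R` | synthesize one subject (8 channels, 3 kHz, 40 trials × 3 × 5 s) and write the TSV/JSON interchange files |
| `analysis/02_preprocess.R` | read back, run the preprocessing chain, write RMS activation ratios |
| `analysis/03_coherence.R` | Welch spectra, coherence + confidence limits, IMC areas, phase-slope delays for that subject |
| `analysis/04_cohort_stats.R` | full 11-subject cohort, rmANOVAs, Holm post hocs, phase tests, figures |

Run them in order with `Rscript analysis/01_simulate.R` etc.

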