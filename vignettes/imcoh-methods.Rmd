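---
title: "Methods: intermuscular coherence estimation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intermuscular coherence estimation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imcoh)
```

## The measurement model

Intermuscular coherence (IMC) rests on a simple idea: if two motoneuron
pools receive a common oscillatory synaptic input, the firing-rate
modulations of their motor units — and hence the envelopes of their surface
EMG — are correlated at the input frequencies. `imcoh` treats the recorded
EMG of muscle $m$ as a broadband carrier (the interference pattern of many
motor-unit action potentials) multiplied by a slow nonnegative envelope
carrying the drive. The analysis chain therefore (1) isolates the envelope,
(2) estimates its cross-spectral structure between muscles, and (3) reduces
the spectra to band summaries suitable for repeated-measures inference.

## Preprocessing chain

The chain is fixed and recorded in each object's provenance:

1. **Decimation** to a 500 Hz working rate with a Chebyshev Type I
   anti-alias low-pass (order 8, 0.05 dB passband ripple, 200 Hz corner) —
   the standard decimation design. We rescale the numerator so the DC gain
   is exactly one; an even-order Chebyshev filter otherwise sits 0.05 dB
   below unity at DC, which would bias constant and near-DC content by a
   few tenths of a percent after forward–backward application.
2. **High-pass** at 20 Hz (4th-order Butterworth), removing movement
   artifact and low-frequency amplitude drift before envelope extraction.
   Channels are demeaned before filtering and residual numerical DC is
   removed after; the 0 Hz bin is deep inside the stopband, so this is a
   numerical clean-up, not a spectral change.
3. **Envelope extraction** as the magnitude of the analytic signal (Hilbert
   rectification). This is applied to the continuous record *before*
   epoching so that analytic-signal edge artifacts arise only at the
   recording ends (first/last 100 ms, flagged in provenance) rather than at
   every trial boundary.
4. **Epoching** into one segment per (trial, movement period) from the
   marker table, concatenated in trial order.

Both filters are applied forward–backward (zero phase). The choice is
deliberate: causal filtering would add a frequency-dependent group delay to
each channel, and although a *common* delay cancels in the cross-spectral
phase, any asymmetry between channels would bias the phase-slope delay
estimates. Note that the envelope's slow fluctuations below 20 Hz are
exactly the object analysed — the 20-Hz high-pass acts on the raw EMG, not
on the envelope, and no additional low-pass is applied to the envelope.

## Spectral estimation

Auto- and cross-spectra are estimated by Welch's method on the concatenated
epochs of one movement period: Hann-windowed, per-segment mean-removed
periodograms, averaged over all segments of all epochs. Defaults are a
500-ms window (2 Hz resolution) and 75% overlap, giving a step of
`floor(0.25 * 250) = 62` samples at 500 Hz — with 5-s epochs, 37 segments
per epoch and 1,480 per period over 40 trials. Two invariants are enforced
by construction and checked in the test suite:

* segments never span an epoch (trial-concatenation) join, because the
  envelope discontinuity at a join would inject spurious coherence;
* the cross-spectral array is Hermitian, so swapping a channel pair
  conjugates `S_xy` and negates the phase.

Magnitude-squared coherence is `|S_xy|^2 / (S_xx S_yy)`, clipped to
\[0, 1\] only against round-off (tolerance 1e−12); self-pairs give exactly 1
at every bin.

## Significance limits and the overlap adjustment

For `N` *independent* segments the null distribution of the coherence
estimate is `P(C > c) = (1 - c)^(N - 1)`, so the level-`alpha` limit is

$$CL_\alpha = 1 - \alpha^{1/(N-1)}.$$

A variant sometimes seen in print, $1-(1-\alpha)^{1/(N-1)}$ with
$\alpha = 0.05$, is *not* a valid limit — for `N = 10` it evaluates to
about 0.006 and declares nearly every bin significant. `imcoh` implements
the Rosenberg form; the other variant is available behind
`confidence_limit(..., variant = "printed")` purely for comparison, and the
Monte-Carlo calibration test demonstrates the difference.

Overlapping segments are correlated, so `N` must be replaced by an
effective count. For a contiguous block yielding `K` overlapped segments at
step `D` with window `w`, we use the equivalent-degrees-of-freedom count

$$N_{\mathrm{eff}} = \frac{K}{1 + 2\sum_{m \ge 1} (1 - m/K)\, c_m},
\qquad c_m = \left(\frac{\sum_n w_n w_{n+mD}}{\sum_n w_n^2}\right)^2,$$

summed over the epochs (correlations do not cross epoch joins). For the
Hann window at 75% overlap and 5-s epochs this inflates the disjoint count
by a factor of ≈ 1.94. The decisive check is empirical: across 200
replicates of independent Gaussian envelopes, the fraction of bins
exceeding the limit must sit within Monte-Carlo error of `alpha` for both
disjoint and overlapped segmentation; the acceptance suite runs exactly
this, and `scripts/acceptance.R` reports the overlapped arm at the study
segmentation (40 epochs × 5 s). Band definitions never include the 0 Hz
bin, so the exceedance fraction is evaluated over all bins above DC.

## Band summaries

* **Band assignment.** Bins with `low <= f <= high` belong to a band; where
  two bands share an edge (beta 13–30 and gamma 30–44 meet at the 30-Hz bin
  on the 2-Hz grid) the shared bin goes to the *upper* band only, so no bin
  is counted twice. With the defaults: alpha {8, 10, 12}, beta {14…28},
  gamma {30…44} Hz.
* **IMC area** sums raw coherence values at bins exceeding the limit. We
  read "summed significant estimates" literally — the alternative of
  summing the *excess* above the limit is available via
  `imc_area(..., variant = "excess")` but is not the default.
* **Log transform** uses an explicit additive offset (default 1e−6) so that
  cells with no significant bins map to `log(offset)` rather than −∞. The
  offset is recorded on the table.
* **Activation ratios** are non-overlapping 50-ms window RMS values
  (trailing partial windows discarded), normalized per muscle to the
  maximum window over the whole recording, averaged per period. A 5-s
  period at 500 Hz yields 100 windows.
* **Phase-slope delays** fit an unweighted least-squares line to the
  unwrapped phase over *all* band bins (a coherence-weighted variant is
  available); delay = slope / 2π, positive when the first channel leads.
  Restricting the fit to significant bins only would make the estimator's
  support data-dependent, so it is not the default.

## Inference layer

Per band, a classical two-way repeated-measures ANOVA (muscle pair ×
movement period) is fitted on log IMC area via `stats::aov` error strata;
delays get the same design, and activation ratios one-way rmANOVAs for
MUSCLE and PERIOD. Uncorrected F tests are reported by default —
sphericity corrections are available (`correction = "GG"`, with the
Greenhouse–Geisser epsilon computed from the per-effect contrast
covariance) but are not the default, matching common practice in the EMG
literature. Post hoc families are all pairwise comparisons within a
significant factor (paired t tests on per-subject cell means), with
interaction follow-ups comparing muscle pairs within each period; each
family is Holm-adjusted. Phase angles are averaged per band (circular mean)
and tested against zero with one-sample t tests. The null calibration of
the two-way design (11 subjects, 4 × 3 cells, 2,000 replicates) is part of
the acceptance suite.

## The synthetic common-drive generator

Because subject-level EMG from the motivating experiments is not publicly
available, validation uses a generator whose defaults encode the
experimental design: 8 channels (VL, VM, TA, ES, left/right) at 3,000 Hz,
40 repetitions of three 5-s periods (ECC, ISO, CON) laid out back-to-back.
Each channel is

$$x_m(t) = \mathrm{carrier}_m(t)\; g_{m,p}\,
\max\Big\{0,\; 1 + \sum_b \gamma_{\mathrm{pair}(m),p,b}\,
d_{\mathrm{pair}(m),b}(t - \tau_{\mathrm{side}(m)}) + \epsilon_m(t)\Big\}$$

with unit-variance band-limited drives $d$ shared within a homologous pair,
coupling gains $\gamma \in [0,1]$, an inter-side delay $\tau$ applied to
the drive only (IMC is computed on envelopes, so only envelope timing
matters), independent envelope noise $\epsilon$, and an independent
20–200 Hz carrier per channel (the carrier band survives both the 200-Hz
anti-alias corner and the 20-Hz high-pass). Design choices worth stating:

* **Multiplicative period gain.** $g_{m,p}$ scales the whole envelope of a
  period, so changing it rescales the channel within that period by a
  constant — amplitude moves, coherence does not. This cleanly encodes the
  amplitude/coherence dissociation (ISO gets the highest default gain, 1.2
  vs 0.8, while couplings peak in ECC for beta/gamma), and makes the
  scale-invariance acceptance check exact rather than approximate.
* **Clipping.** The envelope is clipped at zero; default couplings
  (band-level 0.12–0.18 with pair/period modulation) and noise SD 0.15 keep
  the clipped fraction below 1% of samples, so the nonlinearity is a small
  perturbation (the realized fraction is recorded in the ground truth).
* **Default coupling scheme.** Pair ordering ES > TA > VM > VL and
  beta/gamma elevation during ECC with flat alpha, mirroring the
  qualitative pattern the workflow is meant to resolve; all gains remain
  configurable per (pair, period, band).
* **Default delays are zero** for every pair, so the null behaviour of the
  phase statistics is the default; recovery tests inject nonzero delays
  explicitly.
* **Substreams.** One master seed expands via a pre-drawn seed table to
  per-component substreams (each drive, carrier and noise vector), making
  recordings bitwise reproducible and component-wise stable.
* **Cohort variability.** `run_pipeline` applies lognormal jitter
  (CV 0.2 by default) to coupling gains (per pair) and period gains per
  subject — enough between-subject variance for the repeated-measures
  layer to be meaningfully exercised.

What the generator does *not* emulate: motor-unit action-potential shapes
and recruitment (no biophysical motoneuron pool), volume conduction or
cross-talk between electrodes, nonstationarity within a period, movement
artifact. Passing tests therefore demonstrate that the *estimators* are
correct and calibrated under a realistic signal model — not that any
particular physiological conclusion holds for real recordings.

## Analytic oracles

`linear_envelope_pair` provides a closed-form target for the spectral
chain: with flat in-band spectra for shared drive and channel noises,

$$C = \frac{(g_1 g_2 \sigma_c^2)^2}
{(g_1^2\sigma_c^2 + \sigma_n^2)(g_2^2\sigma_c^2 + \sigma_n^2)},$$

e.g. $C = 1/4$ for $g_1 = g_2 = 1$, $\sigma_c^2 = \sigma_n^2$. The
acceptance suite checks the Welch estimate against this value (±0.05 at
600 s), the direct DFT-product oracle (1e−10 on small inputs), 20-ms delay
recovery (±4 ms in ≥ 90% of 50 replicates), and coupling-gain monotonicity
of IMC area (sign tests across 50 seeds at gains 0/0.3/0.6/0.9).

## Numerical choices and degenerate inputs

* Frequency grid: one-sided, 0–250 Hz at 2 Hz; DC and Nyquist bins are not
  doubled in the density scaling. Bands never touch DC or Nyquist.
* Zero auto-spectrum at any bin, all-zero channels (for activation
  ratios), empty marker tables, epochs shorter than the window, unbalanced
  ANOVA designs and zero-variance t-test samples all raise typed errors
  (`imcoh_*` condition classes) naming the offending entity; nothing is
  silently dropped.
* Constant dependent variables give F = 0, p = 1 by convention (the 0/0
  case).
* Problem sizes in the test suite are scaled down relative to the default
  acquisition (shorter recordings, fewer trials, 2-channel configurations)
  wherever a property does not depend on scale; the structural checks and
  the analysis scripts run the full default layout.

## Interchange formats

Recordings travel as a signal TSV (one column per channel, a `#fs=` header
line) plus a marker TSV (`trial`, `period`, `onset_sample`,
`duration_samples`); ground truth and run provenance as JSON. All result
tables are tidy TSV. An EDF reader is not provided; recorded data should be
converted to the TSV interchange format.

## Known limitations

* The overlap adjustment is an equivalent-degrees-of-freedom
  approximation; it is validated empirically at the default Hann/75%
  setting and standard epoch lengths, and should be re-checked by
  Monte-Carlo if exotic windows or very short epochs are used.
* The envelope-level linear model ignores the carrier's own envelope
  fluctuations, which act as multiplicative noise in real (and simulated)
  EMG; recovered coherence is therefore attenuated relative to the drive
  coherence, which is why recovery tests assert monotonicity and
  calibration rather than exact gain values on the full generative chain.
* Phase-slope delay estimation assumes an approximately linear phase over
  the band; strongly frequency-dependent transmission would bias it.
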