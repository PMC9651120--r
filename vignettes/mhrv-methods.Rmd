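---
title: "Methods: maternal HRV from R-peaks to variance decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: maternal HRV from R-peaks to variance decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhrv)
```

## The problem

Maternal heart rate variability (mHRV) reflects autonomic regulation
during pregnancy and is a candidate screening signal for complications
such as hypertensive disorders. Before absolute mHRV values can be
interpreted clinically, one has to know how much of their variation is
explained by ordinary covariates — maternal age, body mass index (BMI),
gestational age (GA), parity, heart rate (HR), breathing rate (BR) — and
how much is a stable property of the individual woman. This package
implements that analysis end to end: RR-interval cleaning, time-domain
and entropy HRV features, breathing-rate estimation from the tachogram
itself, and a regression layer that decomposes feature variance into
fixed covariate effects and an inter-subject random intercept.

The package consumes maternal R-peak times (seconds). ECG acquisition,
filtering, channel combination and R-peak detection are out of scope;
those stages belong to the upstream recording pipeline.

## Tachogram cleaning

`build_tachogram()` differences R-peak times into RR durations
(milliseconds), each stamped with its onset. Three rejection rules are
applied in a fixed order by `clean_tachogram()`:

1. **Range** — RR outside 0.4–2 s is physiologically implausible and is
   rejected. The bounds themselves are accepted ("outside" is read
   strictly); both bounds are configurable.
2. **Successive difference** — an interval differing by more than 20%
   (strictly) from the reference preceding interval is rejected, the
   classic ectopic-beat rule. The reference is the most recent
   *accepted* interval, so a single ectopic beat does not cascade into
   rejecting the rest of the recording; comparison against the raw
   predecessor is available (`reference = "previous"`).
3. **Neighbour** — a surviving interval whose immediate predecessor and
   successor are both rejected is itself unreliable and is rejected.
   This runs as a single pass; first and last intervals, having only one
   neighbour, are never flagged by it. Iterating the rule to a fixed
   point changes results only on pathological inputs, so the literal
   single pass is used.

Cleaning is a pure function of the RR values, hence idempotent. A
recording with more than 25% rejected intervals fails the reliability
gate (`reliability()`) and is excluded from all downstream analysis;
exactly 25% still passes (strict "more than").

For stages that need a continuous signal, `interpolate_tachogram()`
treats rejected intervals as missing, bridges them linearly between
valid onsets, and resamples at 4 Hz — the conventional grid for HRV
spectral/EMD work; the rate is configurable. A reliability mask marks
grid samples that fall inside rejected spans.

## HRV features

Per measurement, from the surviving normal-to-normal (NN) intervals:

- **SDNN** — sample standard deviation (n−1 denominator, as an estimator
  of the population SD from a finite recording).
- **RMSSD** — root mean square of successive differences, computed only
  between pairs adjacent in the original tachogram with both members
  valid; differencing across a rejected gap would manufacture a spurious
  large difference.
- **SampEn(m, r)** — sample entropy, −ln(A/B), with B the number of
  ordered template pairs (i ≠ j, i, j ≤ N−m) of length m within
  Chebyshev distance r, and A the same for length m+1. Defaults m = 2,
  r = 0.2 × SD of the analysed series — the field-standard setting. The
  analysed series is the concatenated NN intervals, *not* the
  interpolated series: interpolation manufactures regularity and would
  bias entropy downward. An HR-scale option (60000/NN) exists because
  entropy is not invariant under the monotone RR→HR transform.
- **Median HR** — median of 60000/RR over valid intervals, in bpm.

For modelling, SDNN and RMSSD are log-transformed (right-skewed) and
SampEn is squared (left-skewed); `transform_dv()`/`inverse_dv()` hold
the invertible pair.

## Breathing rate by empirical mode decomposition

Respiration is the highest-frequency oscillation contributing to HRV
(respiratory sinus arrhythmia), so the first intrinsic mode function
(IMF) of the resampled tachogram carries the respiratory modulation.
`emd_sift()` implements classical sifting: cubic-spline envelopes
through local maxima/minima, extrema mirror-extended beyond both ends to
suppress spline end swings, iterated until the Cauchy-type criterion
Σ(h_prev−h_new)²/Σh_prev² < 0.2 (hard cap 50 sifts). `emd()` peels IMFs
off successive residues until the residue is monotone; by construction
IMFs plus residue reconstruct the input exactly.

`segment_br()` slides a 120-s window with 50% overlap along the series
(a partial trailing window is dropped — zero-padding would distort
low-frequency content). Windows with more than 5% unreliable samples
are excluded. Otherwise the window's first IMF is extracted, its
instantaneous frequency computed from the FFT analytic signal (wrapped
phase increments × fs/2π, the two edge samples at each end discarded),
samples outside the plausible breathing band 0.1–0.5 Hz are discarded,
and the dominant remaining frequency × 60 is the segment BR. The
measurement's BR is the median over surviving segments
(`median_br()`); when a subject has measurements with no surviving
segment, the mean of her other measurements' medians fills in
(`fallback_br()`).

**Dominant-frequency estimator.** The default is the *median* of the
in-band instantaneous-frequency samples. An amplitude-weighted histogram
mode (0.01 Hz bins) is also provided, but its half-bin quantisation
limits accuracy to ~0.3 brpm, and on tachogram windows — where beat-domain
sampling broadens the instantaneous-frequency distribution — we measured
recurring errors of ~0.9 brpm against ground truth, against ≤0.15 brpm
for the median at typical rates. The median is therefore the default.

**Band-filtering order.** Whether the band limit is applied to the IMF
before frequency analysis or to the frequency samples afterwards is an
open choice; discarding out-of-band frequency samples is the default
(`band_mode = "discard"`), FFT band-passing the IMF first is available
(`"bandpass"`). On clean synthetic signals both agree within tolerance.

## The statistical layer

For each transformed feature y, with covariates age (years), BMI
(kg/m²), GA (decimal weeks), parity (binary nulliparous/parous; numeric
coding optional), median HR (bpm) and median BR (brpm):

- `fit_mlr()` — ordinary least squares with the overall F-test against
  the intercept-only model, adjusted R² = 1 − (1−R²)(n−1)/(n−p−1),
  variance inflation factors VIF_j = 1/(1−R²_j), leverage and Cook's
  distance.
- `fit_lmm()` — random-intercept model y = Xβ + b_subject + ε. The model
  is fitted twice: by **maximum likelihood**, which supplies the
  log-likelihood for the likelihood-ratio test and the reported
  coefficients, and by **REML**, which supplies the reported variance
  components. The reason is estimator bias, not convenience: with q
  between-subject fixed parameters estimated from n subjects, the ML
  σ̂²_b is shrunk by roughly (n−q)/n — at 29 subjects with age, BMI and
  parity in the model this displaces the ICC by ≈ −0.05 at ICC 0.68,
  which REML removes. ML components remain available
  (`sigma2_b_ml`, `icc_ml`).
- **ICC** = σ²_b/(σ²_b+σ²_e): the fraction of residual feature variance
  attributable to stable between-subject differences.
- `lrt()` — 2Δ log-likelihood of ML fits, clipped at zero. Because
  σ²_b = 0 sits on the boundary of its parameter space, the reference
  distribution is the 50:50 mixture of χ²₀ and χ²₁ (at stat = 0 the
  p-value is 1); the naive χ²₁ p-value is reported alongside for
  comparability with software that uses it.
- Fixed-effect intervals and p-values use Satterthwaite-df t quantiles:
  between-subject covariates carry ~n_subjects effective degrees of
  freedom, so plain Wald z intervals measurably under-cover (92.8% at
  the 29×8 design in our calibration runs).
- **Adjusted R² for the LMM** has no single convention; we report
  1 − (SSE/SST)(n−1)/(n−p−1) on conditional (random-effects-included)
  fitted values, plus the Nakagawa marginal/conditional pseudo-R² pair,
  each labelled.
- `effect_curve()` — predictions as one covariate sweeps its 5th–95th
  percentile with the others held at sample medians (binary covariates:
  grid {0, 1}); pointwise 95% bands from the coefficient covariance;
  p-value annotated when < 0.05.
- `remove_influential()` — rows with Cook's D above 1.0 (configurable;
  an advisory list at 4/n is also produced) are removed, at most two by
  default, and the refit is reported with the removed rows itemised.
  Never removes so many rows that the model becomes unidentifiable.
- `chd_screen()` — fits each feature's MLR with and without the
  fetal-CHD flag and reports the drop/keep decision at α = 0.05. No
  multiple-testing correction is applied across the three features
  (stated, not hidden).

## The synthetic-data generator

No clinical recordings ship with the package; every claim is validated
on synthetic data with known ground truth.

- **Cohorts** (`sample_cohort()`): age ~ N(31, 4.5²) truncated to 18–45
  and rounded; BMI log-normal with median 22.8; parity 0/1/2 with
  probabilities 0.55/0.35/0.10; fetal-CHD prevalence 26.9% in the
  single-measurement design, 0 in the repeated design. These defaults
  place the simulated medians inside the interquartile ranges reported
  for healthy pregnant cohorts. The repeated design schedules visits at
  ≈14, 18, 22, 24, 26, 30, 34, 36, 38, 40 weeks GA with 20% independent
  per-visit dropout, giving the observed median of ~8 measurements per
  subject.
- **Feature-level generator** (`simulate_features()`): per-measurement
  HR and BR from truncated normals centred at 78 bpm and 14 brpm; then
  y = β₀ + Xβ + b + ε with b ~ N(0, σ²_b), ε ~ N(0, σ²_e). Default β
  place HR as the dominant (negative) effect and centre the response at
  the published feature medians; σ²_b + σ²_e defaults per feature with
  the split set by the target ICC (defaults 0.48/0.68/0.28 for
  SDNN/RMSSD/SampEn).
- **Signal-level generator** (`simulate_rr()`): beat-by-beat,
  RR(t) = base + A_rsa sin(2π f_br t) + A_lf sin(2π·0.1·t + φ) + noise.
  Additive sinusoidal modulation is chosen over an
  integral-pulse-frequency-modulation heart model because it gives
  analytic ground truth for the breathing rate and the variance
  structure — sufficient to exercise every pipeline stage, but it does
  not reproduce the 1/f background, nonstationarity, or waveform-level
  artifacts of real recordings. Defaults: 30-minute duration, base RR
  770 ms (≈78 bpm), RSA amplitude 30 ms, BR 14 brpm, slow-modulation
  amplitude 25 ms, beat noise 2 ms.
- **Artifacts** (`inject_artifacts()`): each interior beat is corrupted
  with the configured probability — deleted (missed beat → one long
  interval) or a spurious mid-interval peak inserted (→ two short
  intervals), with a truth mask over the corrupted intervals.

What passing tests on this generator shows: the estimators recover known
parameters under the stated noise model at the stated design sizes. What
it does not show: robustness to real abdominal-ECG artifact structure,
breathing irregularity, or drift beyond the modelled slow modulation.

## Validation conditions and problem sizes

The test-suite calibration runs use the repeated design at 29 subjects ×
8 measurements (an 8-visit schedule without dropout for exact balance)
and the single design at 290 subjects — the two shapes of the cohorts the
analysis is designed for. ICC recovery is averaged over 200 replicates at
generating values 0.28, 0.48, 0.68; CI coverage uses 500 replicates per
design; F-test size 1000 null replicates; LRT power 100 replicates at
ICC 0.5. Breathing-rate recovery uses 10-minute RSA-only tachograms
(no artifacts, no noise, no slow modulation) at 9, 12, 15, 18 and
24 brpm, with the slow-modulation separation checked separately by a
0.01 Hz trend-invariance test, and artifact sensitivity uses a 5%
corruption rate. These sizes keep every simulated check well-powered
while remaining quick to run.

## Numerical choices and degenerate inputs

- SampEn with no matching template pair (A or B zero) is reported as
  missing, never as infinity; zero-variance series are an error because
  the tolerance r = 0.2 × SD degenerates.
- A monotone (or all-zero) signal yields zero IMFs and residue equal to
  the input; sifting stops when fewer than two interior maxima or minima
  remain.
- Exact collinearity yields an infinite VIF and a rank-deficiency error
  naming the offending columns in `fit_mlr()`; the orchestrator drops
  unidentifiable covariates (QR pivoting) with a logged message rather
  than failing a whole run on a tiny cohort.
- The LRT statistic is clipped at zero (ML optima can differ by
  floating-point noise on boundary fits).
- Ties in the dominant-frequency histogram resolve to the lower bin
  (`which.max`); the median estimator has no ties to break.

## Known limitations

- The RR generator's additive-sinusoidal model understates the
  complexity of real maternal tachograms; entropy values from it should
  not be read as physiologically representative.
- Breathing-rate estimation degrades near the band edges: at 24 brpm
  (0.4 Hz) the 4 Hz grid leaves 10 samples per breath and the estimate
  biases low by ~0.6 brpm.
- The mixed model is a random-intercept model only: no random slopes,
  no GA splines, no crossed effects — matching the analysis it
  implements, not the space of models one might fit to such data.
- With 29 subjects, between-subject effects (age, BMI, parity) are
  estimated with few effective degrees of freedom; their interval
  estimates are honest but wide.
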